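# Signed-rank gene signatures: the query objects for connectivity mapping.

#' Construct a signed-rank gene signature
#'
#' A signature is an ordered list of genes with nonzero integer ranks:
#' positive ranks mark genes up-regulated with disease development and
#' progression, negative ranks down-regulated genes, and the magnitude
#' encodes the within-direction importance (largest = most significant).
#' Positive magnitudes must form the contiguous set `1..n_up` and negative
#' magnitudes `1..n_down`.
#'
#' The scoring engine accepts arbitrary nonzero signed-rank multisets, so
#' contiguity is only enforced when `strict = TRUE` (as used by
#' [build_signatures()] for derived signatures).
#'
#' @param gene_ids Character vector of unique gene ids.
#' @param ranks Integer vector of signed ranks, same length.
#' @param signature_id Identifier string.
#' @param strict Enforce per-direction contiguous rank magnitudes.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(gene_ids, ranks, signature_id = "signature",
                           strict = FALSE) {
  gene_ids <- as.character(gene_ids)
  ranks <- as.integer(ranks)
  if (length(gene_ids) != length(ranks) || length(gene_ids) == 0L) {
    stop("gene_ids and ranks must be nonempty and of equal length",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("signature gene ids must be unique", call. = FALSE)
  }
  if (any(ranks == 0L)) stop("signature ranks must be nonzero", call. = FALSE)
  if (strict) {
    pos <- sort(ranks[ranks > 0L])
    neg <- sort(-ranks[ranks < 0L])
    if ((length(pos) && !identical(pos, seq_along(pos))) ||
        (length(neg) && !identical(neg, seq_along(neg)))) {
      stop("rank magnitudes must be contiguous 1..n within each direction",
           call. = FALSE)
    }
  }
  structure(list(entries = data.frame(gene_id = gene_ids, rank = ranks,
                                      stringsAsFactors = FALSE),
                 signature_id = as.character(signature_id)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  n_up <- sum(x$entries$rank > 0)
  n_down <- sum(x$entries$rank < 0)
  cat(sprintf("gene_signature '%s': %d genes (%d up, %d down)\n",
              x$signature_id, nrow(x$entries), n_up, n_down))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) nrow(x$entries)

#' Build nested derivative signatures from ranked gene lists
#'
#' From the monotonically increasing and decreasing gene lists (each
#' ordered most-significant first), takes the top `d` genes of each list
#' for every requested depth `d` and assigns signed ranks per direction:
#' the most significant increasing gene receives `+d`, the next `+(d-1)`,
#' down to `+1`; decreasing genes receive the negated ranks. Because the
#' lists are fixed, the signatures are nested: every gene of the depth-10
#' signature appears in the depth-20 signature and so on.
#'
#' @param increasing,decreasing Character vectors from [monotone_filter()]
#'   (after any [restrict_universe()]), most significant gene first.
#' @param depths Per-direction depths; the default `c(10, 20, 30, 40, 50)`
#'   yields the five derivative signatures of 20, 40, 60, 80 and 100
#'   genes. A depth exceeding either list length is skipped with a
#'   warning.
#' @return Named list of [gene_signature()]s (names `top10`, `top20`, ...).
#' @export
build_signatures <- function(increasing, decreasing,
                             depths = c(10L, 20L, 30L, 40L, 50L)) {
  depths <- sort(unique(vapply(seq_along(depths), function(i) {
    check_count(depths[i], sprintf("depths[%d]", i))
  }, integer(1))))
  out <- list()
  for (d in depths) {
    if (length(increasing) < d || length(decreasing) < d) {
      warning(sprintf(
        "depth %d skipped: lists have %d increasing / %d decreasing genes",
        d, length(increasing), length(decreasing)), call. = FALSE)
      next
    }
    id <- sprintf("top%d", d)
    out[[id]] <- gene_signature(
      gene_ids = c(increasing[seq_len(d)], decreasing[seq_len(d)]),
      ranks = c(seq.int(d, 1L), -seq.int(d, 1L)),
      signature_id = id,
      strict = TRUE
    )
  }
  out
}
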