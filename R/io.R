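# Plain-text (TSV) readers and writers for every pipeline artifact.

write_tsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' Read / write an expression matrix TSV
#'
#' The on-disk layout has a first column `gene_id` followed by one column
#' per sample, log2-scale values.
#'
#' @param X Numeric matrix, genes x samples.
#' @param path File path.
#' @return `read_expression_tsv` returns the matrix with gene rownames.
#' @export
write_expression_tsv <- function(X, path) {
  write_tsv(data.frame(gene_id = rownames(X), X, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  X <- as.matrix(d[, -1L, drop = FALSE])
  rownames(X) <- d$gene_id
  X
}

#' Read / write a sample annotation TSV
#'
#' Columns `sample_id` and `group`; the stage order is supplied on read
#' (defaults to the standard five-stage design).
#'
#' @param annotation data.frame with `sample_id` and `group`.
#' @param path File path.
#' @param group_order Ordered stage labels used as factor levels on read.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write_tsv(data.frame(sample_id = annotation$sample_id,
                       group = as.character(annotation$group)), path)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path,
                                group_order = c("normal", "low", "medium",
                                                "high", "AML")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  extra <- setdiff(unique(d$group), group_order)
  if (length(extra)) {
    stop(sprintf("groups not in group_order: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  d$group <- factor(d$group, levels = group_order)
  d
}

#' Read / write a gene signature
#'
#' Signatures are stored as headerless two-column tab-delimited files
#' (`gene_id` TAB `signed_rank`), the format the connectivity-mapping
#' tooling consumes, with a small JSON sidecar (`<path>.json`) recording
#' the signature id.
#'
#' @param sig A [gene_signature()].
#' @param path File path.
#' @param signature_id Used on read when no sidecar exists; defaults to
#'   the file name.
#' @export
write_signature_tsv <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  write_tsv(sig$entries, path, col.names = FALSE)
  jsonlite::write_json(list(signature_id = sig$signature_id,
                            n_genes = nrow(sig$entries)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path, signature_id = NULL) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("gene_id", "rank"),
                         stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (is.null(signature_id)) {
    signature_id <- if (file.exists(sidecar)) {
      jsonlite::read_json(sidecar)$signature_id
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  gene_signature(d$gene_id, d$rank, signature_id)
}

#' Read / write a reference set directory
#'
#' On disk a refset is a directory holding `universe.txt` (one gene id per
#' line), `index.tsv` (`instance_id`, `perturbagen`, `cell_line`, `dose`)
#' and `profiles/<instance_id>.tsv` headerless two-column files
#' (`gene_id` TAB `signed_rank`).
#'
#' @param rs A [refset()].
#' @param dir Directory path (created if needed).
#' @export
write_refset_dir <- function(rs, dir) {
  stopifnot(inherits(rs, "refset"))
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  writeLines(rs$universe, file.path(dir, "universe.txt"))
  write_tsv(rs$index, file.path(dir, "index.tsv"))
  for (j in seq_len(ncol(rs$ranks))) {
    write_tsv(data.frame(gene_id = rs$universe, rank = rs$ranks[, j]),
              file.path(dir, "profiles",
                        paste0(rs$index$instance_id[j], ".tsv")),
              col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_refset_dir
#' @export
read_refset_dir <- function(dir) {
  universe <- readLines(file.path(dir, "universe.txt"))
  index <- utils::read.delim(file.path(dir, "index.tsv"),
                             stringsAsFactors = FALSE)
  ranks <- vapply(index$instance_id, function(id) {
    d <- utils::read.delim(file.path(dir, "profiles", paste0(id, ".tsv")),
                           header = FALSE,
                           col.names = c("gene_id", "rank"),
                           stringsAsFactors = FALSE)
    r <- d$rank[match(universe, d$gene_id)]
    if (anyNA(r)) {
      stop(sprintf("profile %s does not cover the universe", id),
           call. = FALSE)
    }
    as.integer(r)
  }, integer(length(universe)))
  rownames(ranks) <- universe
  refset(ranks, index, provenance = dir)
}

#' Read / write a viability table TSV
#'
#' Single-agent (`drug`, `dose`, `replicate`, `rlu`) or combination
#' (`drug1`, `dose1`, `drug2`, `dose2`, `replicate`, `rlu`) layouts.
#'
#' @param table Viability data.frame.
#' @param path File path.
#' @export
write_viability_tsv <- function(table, path) {
  write_tsv(table, path)
  invisible(path)
}

#' @rdname write_viability_tsv
#' @export
read_viability_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
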