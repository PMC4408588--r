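# Plain-text readers and writers for every pipeline container. All
# formats are tab-separated with a header; CDS sequences travel as FASTA.

#' Write / read a gene catalog TSV (CDS excluded; see [write_cds_fasta()])
#' @param catalog A `gene_catalog`.
#' @param path Output TSV path.
#' @return The path (write) or a `gene_catalog` (read), invisibly for
#'   writers.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(catalog[, setdiff(names(catalog), "cds")], path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Write catalog coding sequences as FASTA
#' @param catalog A `gene_catalog` with a `cds` column.
#' @param path Output FASTA path.
#' @export
write_cds_fasta <- function(catalog, path) {
  seqs <- Biostrings::DNAStringSet(setNames(catalog$cds,
                                            catalog$gene_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read coding sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write / read a sample sheet TSV
#' @param sheet A `sample_sheet`.
#' @param path TSV path.
#' @export
write_sample_sheet <- function(sheet, path) write_tsv(sheet, path)

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  out <- read_tsv(path)
  need <- c("array_id", "condition", "replicate", "fraction",
            "dye_orientation")
  if (!all(need %in% names(out))) {
    stop("sample sheet must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Write / read raw intensities in long format
#'
#' Long format: one row per (gene_id, array_id, channel) with the raw
#' intensity, channel in \{red, green\}.
#'
#' @param im An `intensity_matrix`.
#' @param path TSV path.
#' @export
write_intensities <- function(im, path) {
  long <- rbind(
    data.frame(gene_id = rep(im$genes, ncol(im$red)),
               array_id = rep(colnames(im$red), each = length(im$genes)),
               channel = "red", intensity = as.vector(im$red),
               stringsAsFactors = FALSE),
    data.frame(gene_id = rep(im$genes, ncol(im$green)),
               array_id = rep(colnames(im$green),
                              each = length(im$genes)),
               channel = "green", intensity = as.vector(im$green),
               stringsAsFactors = FALSE)
  )
  write_tsv(long, path)
}

#' @rdname write_intensities
#' @param sheet The matching `sample_sheet` (defines array order).
#' @export
read_intensities <- function(path, sheet) {
  long <- read_tsv(path)
  genes <- unique(long$gene_id)
  arrays <- sheet$array_id
  shape <- function(chan) {
    sub <- long[long$channel == chan, ]
    m <- matrix(NA_real_, length(genes), length(arrays),
                dimnames = list(genes, arrays))
    m[cbind(match(sub$gene_id, genes), match(sub$array_id, arrays))] <-
      sub$intensity
    m
  }
  red <- shape("red"); green <- shape("green")
  if (anyNA(red) || anyNA(green)) {
    stop("intensity table does not cover every gene x array x channel",
         call. = FALSE)
  }
  structure(list(red = red, green = green, genes = genes, sheet = sheet),
            class = "intensity_matrix")
}

#' Write / read a profile trace TSV (position, absorbance)
#' @param trace A `profile_trace`.
#' @param path TSV path.
#' @export
write_trace <- function(trace, path) {
  write_tsv(data.frame(position = trace$position,
                       absorbance = trace$absorbance), path)
}

#' Write the ground truth as TSV (long format)
#' @param truth A `ground_truth`.
#' @param path TSV path.
#' @export
write_ground_truth <- function(truth, path) {
  conds <- colnames(truth$log2fc)
  long <- do.call(rbind, lapply(conds, function(cc) {
    data.frame(gene_id = rownames(truth$log2fc), condition = cc,
               transcriptional_log2fc = truth$log2fc[, cc],
               translational_state_true = truth$ts[, cc],
               pm_ratio_true = truth$pm_ratio[[cc]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(long, path)
}

#' Write / read an expression table (normalized log2 ratios)
#' @param expr An `expr_table`.
#' @param path TSV path for the matrix; metadata goes in the first three
#'   header-encoded columns.
#' @export
write_expr_table <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$E), expr$E,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expr_table
#' @export
read_expr_table <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  e <- as.matrix(df[, -1, drop = FALSE])
  rownames(e) <- df$gene_id
  parts <- strsplit(colnames(e), ".", fixed = TRUE)
  samples <- data.frame(
    sample_id = colnames(e),
    condition = vapply(parts, `[`, character(1), 1),
    replicate = as.integer(vapply(parts, `[`, character(1), 2)),
    fraction = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  new_expr_table(e, samples)
}
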