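#' Construct a quantification matrix
#'
#' A `quant_matrix` holds protein-by-sample log2-scale abundances for one
#' fraction of a paired fractionation experiment. Missing values are `NA`;
#' all non-missing values must be finite, and protein and sample
#' identifiers must be unique.
#'
#' @param values Numeric matrix with protein identifiers as rownames and
#'   sample identifiers as colnames. `NA` marks a missing quantification.
#' @param fraction Fraction label, typically `"lysate"` or `"mito"`
#'   (any other organelle label is accepted).
#' @return An object of class `quant_matrix` (a numeric matrix with a
#'   `fraction` attribute).
#' @export
quant_matrix <- function(values, fraction) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("`values` must carry protein rownames")
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("`values` must carry sample colnames")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(character(0), character(0))
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein identifier(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite, non-missing values are not allowed")
  if (!is.character(fraction) || length(fraction) != 1L || !nzchar(fraction))
    stop("`fraction` must be a single non-empty label")
  structure(values, fraction = fraction, class = c("quant_matrix", "matrix", "array"))
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix [%s]: %d proteins x %d samples, %d missing (%.1f%%)\n",
              attr(x, "fraction"), nrow(x), ncol(x), sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @rdname quant_matrix
#' @param x Object to test.
#' @export
is_quant_matrix <- function(x) inherits(x, "quant_matrix")

#' Read a quantification matrix from TSV
#'
#' Expected layout: first column protein identifier, remaining columns one
#' per sample; empty cells mark missing quantifications; dot decimal
#' separator; UTF-8.
#'
#' @param path Path to a tab-separated file.
#' @param fraction Fraction label attached to the result.
#' @return A [quant_matrix].
#' @export
read_quant_matrix <- function(path, fraction) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("matrix TSV needs a protein column plus >=1 sample column")
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate protein identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    cell <- trimws(df[[j + 1L]])
    empty <- !nzchar(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d (protein '%s'), column '%s': '%s'",
                   bad[1L], ids[bad[1L]], samples[j], cell[bad[1L]]))
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  quant_matrix(vals, fraction)
}

#' Write a quantification (or enrichment) matrix to TSV
#'
#' Inverse of [read_quant_matrix()]: missing values become empty cells, so
#' a write/read round trip is lossless for values, mask and ordering.
#'
#' @param m Matrix with dimnames (a [quant_matrix] or plain matrix).
#' @param path Output path.
#' @param id_column Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(m, path, id_column = "protein_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `subject_id`, `genotype`, `condition`, `cohort`,
#' optional `pair_id` (empty when unpaired) and `replicate` (0/1).
#' Each non-empty `pair_id` must occur exactly twice, with differing
#' `condition` labels (tumor/adjacent style pairing).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df A data.frame with the columns described above.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "subject_id", "genotype", "condition", "cohort")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!"pair_id" %in% colnames(df)) df$pair_id <- ""
  if (!"replicate" %in% colnames(df)) df$replicate <- "0"
  df$pair_id[is.na(df$pair_id)] <- ""
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  pid <- df$pair_id[nzchar(df$pair_id)]
  if (length(pid)) {
    tab <- table(pid)
    if (any(tab != 2L))
      stop("pair_id(s) not occurring exactly twice: ",
           paste(names(tab)[tab != 2L], collapse = ", "))
    for (p in names(tab)) {
      cond <- df$condition[df$pair_id == p]
      if (cond[1L] == cond[2L])
        stop("pair '", p, "' has identical condition labels")
    }
  }
  df$replicate <- as.integer(df$replicate)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param meta A `sample_metadata` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Align two fraction matrices on shared proteins and samples
#'
#' Restricts both matrices to their shared proteins and shared samples in
#' canonical (lexicographic) order and reports the proteins exclusive to
#' either fraction. Missing values pass through untouched.
#'
#' @param mito `quant_matrix` for the organelle-enriched fraction.
#' @param lysate `quant_matrix` for the total lysate.
#' @param meta Optional `sample_metadata`; when given, every sample in
#'   either matrix must be present in it.
#' @return A list of class `aligned_pair` with elements `mito`, `lysate`,
#'   `exclusive_to_mito`, `exclusive_to_lysate`.
#' @export
align_fractions <- function(mito, lysate, meta = NULL) {
  stopifnot(is_quant_matrix(mito), is_quant_matrix(lysate))
  if (!is.null(meta)) {
    all_s <- union(colnames(mito), colnames(lysate))
    absent <- setdiff(all_s, meta$sample_id)
    if (length(absent))
      stop("sample(s) absent from metadata: ", paste(absent, collapse = ", "))
  }
  shared_p <- sort(intersect(rownames(mito), rownames(lysate)))
  shared_s <- sort(intersect(colnames(mito), colnames(lysate)))
  if (!length(shared_p)) stop("no shared proteins between fractions")
  if (!length(shared_s)) stop("no shared samples between fractions")
  out <- list(
    mito = quant_matrix(unclass(mito)[shared_p, shared_s, drop = FALSE],
                        attr(mito, "fraction")),
    lysate = quant_matrix(unclass(lysate)[shared_p, shared_s, drop = FALSE],
                          attr(lysate, "fraction")),
    exclusive_to_mito = sort(setdiff(rownames(mito), shared_p)),
    exclusive_to_lysate = sort(setdiff(rownames(lysate), shared_p))
  )
  class(out) <- "aligned_pair"
  out
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf(
    "aligned_pair: %d shared proteins x %d samples; %d exclusive to %s, %d exclusive to %s\n",
    nrow(x$mito), ncol(x$mito),
    length(x$exclusive_to_mito), attr(x$mito, "fraction"),
    length(x$exclusive_to_lysate), attr(x$lysate, "fraction")))
  invisible(x)
}

#' Drop proteins quantified in too few samples
#'
#' Retains rows whose proportion of non-missing values is at least
#' `min_fraction_present` (mirrors the common DIA practice of keeping
#' features identified in at least 10% of runs). Row order is preserved
#' and the operation is idempotent.
#'
#' @param m A [quant_matrix].
#' @param min_fraction_present Threshold in (0, 1].
#' @return Filtered [quant_matrix].
#' @export
filter_by_presence <- function(m, min_fraction_present = 0.10) {
  stopifnot(is_quant_matrix(m))
  if (!is.numeric(min_fraction_present) || length(min_fraction_present) != 1L ||
      min_fraction_present <= 0 || min_fraction_present > 1)
    stop("`min_fraction_present` must lie in (0, 1]")
  keep <- rowMeans(!is.na(m)) >= min_fraction_present
  quant_matrix(unclass(m)[keep, , drop = FALSE], attr(m, "fraction"))
}

#' Per-sample median centering within a fraction
#'
#' Optional normalization (off by default in the pipeline: equal peptide
#' amounts are injected per fraction, so matrices are comparable as-is).
#' Subtracts each sample's median log2 abundance.
#'
#' @param m A [quant_matrix].
#' @return Centered [quant_matrix].
#' @export
median_center <- function(m) {
  stopifnot(is_quant_matrix(m))
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  quant_matrix(sweep(unclass(m), 2L, med, "-"), attr(m, "fraction"))
}

#' Log2-transform a linear-scale matrix
#'
#' For inputs not already on log2 scale. Non-positive values are raised to
#' `pseudo_floor` before taking log2.
#'
#' @param m A [quant_matrix] of linear-scale intensities.
#' @param pseudo_floor Positive floor applied to non-positive cells.
#' @return Log2-scale [quant_matrix].
#' @export
log2_transform <- function(m, pseudo_floor = 1) {
  stopifnot(is_quant_matrix(m), pseudo_floor > 0)
  v <- unclass(m)
  v[!is.na(v) & v < pseudo_floor] <- pseudo_floor
  quant_matrix(log2(v), attr(m, "fraction"))
}

#' Read organelle marker panels from a GMT file
#'
#' One panel per line: name TAB description TAB member ...; the
#' description field is used as the organelle label. Duplicate members
#' within a line are deduplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return List of `marker_panel` objects (each a list with `name`,
#'   `organelle`, `members`), named by panel name.
#' @export
read_marker_panels_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  panels <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 member",
                   i, length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate member(s) removed", i, fields[1L]))
      members <- unique(members)
    }
    panels[[fields[1L]]] <- marker_panel(fields[1L], fields[2L], members)
  }
  panels
}

#' @rdname read_marker_panels_gmt
#' @param name Panel name.
#' @param organelle Organelle label.
#' @param members Character vector of member identifiers (unique, non-empty).
#' @export
marker_panel <- function(name, organelle, members) {
  members <- unique(as.character(members))
  if (!length(members)) stop("marker panel '", name, "' is empty")
  structure(list(name = name, organelle = organelle, members = members),
            class = "marker_panel")
}

#' Write marker panels to a GMT file
#' @param panels List of `marker_panel` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_panels_gmt <- function(panels, path) {
  lines <- vapply(panels, function(p)
    paste(c(p$name, p$organelle, p$members), collapse = "\t"), character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
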