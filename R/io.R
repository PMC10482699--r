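#' Construct a validated taxon-by-sample count table
#'
#' The central community-data container: a non-negative integer matrix with
#' taxa as rows and samples as columns, tagged with the nucleic acid the
#' library was built from (DNA or cDNA from rRNA).
#'
#' @param counts numeric matrix, taxa x samples, with unique rownames
#'   (taxon identifiers) and colnames (sample identifiers). Values must be
#'   non-negative integers; every sample column must have total count >= 1.
#' @param kind `"DNA"` or `"RNA"`.
#' @return An integer matrix of class `"count_table"` with a `kind` attribute.
#' @export
count_table <- function(counts, kind = c("DNA", "RNA")) {
  kind <- match.arg(kind)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integer-valued")
  empty <- colSums(counts) < 1
  if (any(empty))
    stop("empty sample column(s): ", paste(colnames(counts)[empty], collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(counts, kind = kind, class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d taxa x %d samples, total reads %s\n",
              attr(x, "kind"), nrow(x), ncol(x),
              format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read a tab-separated count table
#'
#' Expects taxa as rows: first column taxon identifiers, header row sample
#' identifiers. UTF-8; Unix or Windows line endings.
#'
#' @param path path to the TSV file.
#' @param kind `"DNA"` or `"RNA"`.
#' @return a [count_table].
#' @export
read_count_table <- function(path, kind = c("DNA", "RNA")) {
  kind <- match.arg(kind)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("count table needs a taxon column plus >=1 sample column")
  taxa <- raw[[1]]
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                dimnames = list(taxa, colnames(raw)[-1]))
  for (j in seq_len(ncol(raw) - 1L)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': '%s'",
                   taxa[bad[1]], colnames(raw)[j + 1L], raw[[j + 1L]][bad[1]]))
    mat[, j] <- v
  }
  count_table(mat, kind)
}

#' Write a count table as TSV (round-trips with [read_count_table])
#' @param x a [count_table].
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(taxon_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read ASV sequences plus predicted 16S rRNA gene copy numbers
#'
#' @param fasta_path FASTA of representative sequences; headers are taxon ids.
#' @param copy_number_path TSV with columns `taxon_id` and `copy_number`
#'   (predicted 16S rRNA gene copies per genome, >= 1).
#' @return data.frame with columns taxon_id, sequence (uppercase ACGT),
#'   copy_number.
#' @export
read_taxa_fasta <- function(fasta_path, copy_number_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequence <- toupper(as.character(seqs))
  if (any(nchar(sequence) == 0))
    stop("empty sequence record(s): ", paste(ids[nchar(sequence) == 0], collapse = ", "))
  if (any(grepl("[^ACGT]", sequence)))
    stop("sequence(s) with characters outside {A,C,G,T}: ",
         paste(ids[grepl("[^ACGT]", sequence)], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate taxon ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- utils::read.table(copy_number_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("taxon_id", "copy_number") %in% colnames(cn)))
    stop("copy-number table needs columns 'taxon_id' and 'copy_number'")
  missing <- setdiff(ids, cn$taxon_id)
  if (length(missing))
    stop("taxa in FASTA missing from copy-number table: ",
         paste(missing, collapse = ", "))
  copy <- cn$copy_number[match(ids, cn$taxon_id)]
  if (any(!is.finite(copy) | copy < 1))
    stop("predicted copy numbers must be finite and >= 1")
  data.frame(taxon_id = ids, sequence = sequence, copy_number = copy,
             stringsAsFactors = FALSE)
}

#' Write taxa as FASTA
#' @param taxa data.frame with taxon_id and sequence columns.
#' @param path output path.
#' @export
write_taxa_fasta <- function(taxa, path) {
  ss <- Biostrings::BStringSet(taxa$sequence)
  names(ss) <- taxa$taxon_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Columns every sample-metadata table must carry, with their parsed type.
.sample_cols <- c(
  sample_id = "character", site_id = "character", treatment = "character",
  horizon = "character", timepoint = "character", inoculation = "character",
  pH = "numeric", max_temp_C = "numeric", vegetation = "character",
  years_post_fire = "numeric", burn_severity_index = "numeric",
  qpcr_total_copies_per_g = "numeric"
)

#' Read and validate per-sample experimental metadata
#'
#' CSV with one row per sample. Missing values are empty cells; any other
#' sentinel in a numeric column is a parse error. Field samples must carry a
#' burn severity index and years post-fire; lab samples must not. Burned lab
#' cores must carry a maximum thermocouple temperature.
#'
#' @param path path to the CSV file.
#' @return validated data.frame of sample records.
#' @export
read_sample_metadata <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(.sample_cols), colnames(raw))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- raw[names(.sample_cols)]
  for (col in names(.sample_cols)) {
    if (.sample_cols[[col]] == "numeric") {
      v <- trimws(out[[col]])
      num <- suppressWarnings(as.numeric(v))
      bad <- which(v != "" & is.na(num))
      if (length(bad))
        stop(sprintf("metadata column '%s' row %d: '%s' is not numeric or empty",
                     col, bad[1], v[bad[1]]))
      num[v == ""] <- NA_real_
      out[[col]] <- num
    }
  }
  validate_sample_metadata(out)
}

#' Validate a sample-metadata data.frame (see [read_sample_metadata])
#' @param samples data.frame of sample records.
#' @return the input, invisibly validated (returned unchanged).
#' @export
validate_sample_metadata <- function(samples) {
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata")
  ok_treat <- c("unburned", "moist_burn", "dry_burn")
  if (!all(samples$treatment %in% ok_treat))
    stop("treatment must be one of: ", paste(ok_treat, collapse = ", "))
  if (!all(samples$horizon %in% c("organic", "mineral")))
    stop("horizon must be 'organic' or 'mineral'")
  if (!all(samples$timepoint %in% c("t24h", "t5wk", "t6mo", "field")))
    stop("timepoint must be one of t24h, t5wk, t6mo, field")
  is_field <- samples$timepoint == "field"
  if (any(is_field & (is.na(samples$burn_severity_index) | is.na(samples$years_post_fire))))
    stop("field samples require burn_severity_index and years_post_fire")
  if (any(!is_field & (!is.na(samples$burn_severity_index) | !is.na(samples$years_post_fire))))
    stop("burn_severity_index / years_post_fire only allowed for field samples")
  sev <- samples$burn_severity_index
  if (any(!is.na(sev) & (sev < 0 | sev > 5)))
    stop("burn_severity_index must lie in [0, 5]")
  lab_burned <- !is_field & samples$treatment != "unburned"
  if (any(lab_burned & is.na(samples$max_temp_C)))
    stop("burned lab cores require max_temp_C: ",
         paste(samples$sample_id[lab_burned & is.na(samples$max_temp_C)], collapse = ", "))
  samples
}

#' Join a count table with its sample metadata
#'
#' Every sample column must have a metadata row; unmatched samples are an
#' error (silent drops would corrupt paired contrasts).
#'
#' @param table a [count_table].
#' @param samples metadata data.frame.
#' @return metadata rows reordered to the table's sample columns.
#' @export
align_samples <- function(table, samples) {
  missing <- setdiff(colnames(table), samples$sample_id)
  if (length(missing))
    stop("samples in count table without metadata: ", paste(missing, collapse = ", "))
  samples[match(colnames(table), samples$sample_id), , drop = FALSE]
}

#' Per-sample relative abundances
#'
#' @param table a [count_table] (or bare counts matrix with positive column
#'   totals).
#' @return numeric matrix of the same shape; each column sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  attr(m, "kind") <- NULL
  storage.mode(m) <- "double"
  sweep(m, 2L, colSums(m), "/")
}

#' Read CO2 flux series from long-format CSV
#'
#' Columns: `sample_id`, `time` (days), `flux` (mg CO2-C per g initial total C
#' per day). Returns a list of per-sample series.
#'
#' @param path CSV path.
#' @param min_obs minimum observations per series (series used for two-pool
#'   fitting need at least 6).
#' @return named list of data.frames (time, flux), times strictly increasing.
#' @export
read_flux_csv <- function(path, min_obs = 6L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "time", "flux")
  if (!all(need %in% colnames(df)))
    stop("flux CSV needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("flux CSV is empty")
  out <- lapply(split(df[c("time", "flux")], df$sample_id), function(s) {
    s <- s[order(s$time), , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  for (id in names(out)) {
    s <- out[[id]]
    if (nrow(s) < min_obs)
      stop(sprintf("flux series '%s' has %d observations; >= %d required",
                   id, nrow(s), min_obs))
    if (any(diff(s$time) <= 0)) stop("flux series '", id, "': times not strictly increasing")
    if (any(s$time < 0) || any(s$flux < 0) || anyNA(s$flux))
      stop("flux series '", id, "': negative or missing values")
  }
  out
}

#' Radiant energy delivered by a burn protocol
#'
#' Cumulative radiant exposure of a constant-intensity heat flux, in MJ per
#' square metre; used to check burn-protocol configurations against the target
#' exposure of simulated fires (60 kW m-2 held for 2 min delivers 7.2 MJ m-2).
#'
#' @param intensity_kW_m2 radiant heat flux, kW m-2 (>= 0).
#' @param duration_s exposure time, seconds (>= 0).
#' @return energy in MJ m-2.
#' @export
radiant_exposure <- function(intensity_kW_m2, duration_s) {
  if (any(intensity_kW_m2 < 0) || any(duration_s < 0))
    stop("intensity and duration must be non-negative")
  intensity_kW_m2 * duration_s / 1000
}
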