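# Plain-text readers/writers. Universal dialect: tab-separated values with
# '#' comment lines; chemical shifts to 4 decimal places, other numeric
# columns at full (round-trip exact) precision.

.peak_cols <- c("residue_index", "residue_code", "atom", "shift_ppm")

#' Validate a peak-list data.frame
#'
#' Checks the peak-list contract used throughout the package: required
#' columns `residue_index`, `residue_code`, `atom`, `shift_ppm` (optional
#' `intensity` and `state`), finite shifts, and no duplicate
#' (residue, atom, state) entries.
#'
#' @param x a data.frame.
#' @return `x`, with `residue_index` coerced to integer.
#' @export
validate_peak_list <- function(x) {
  if (!is.data.frame(x)) stop_invalid("peak list must be a data.frame")
  missing_c <- setdiff(.peak_cols, names(x))
  if (length(missing_c))
    stop_invalid("peak list lacks column(s): %s",
                 paste(missing_c, collapse = ", "))
  if (nrow(x) == 0L) return(x)
  if (any(!is.finite(x$shift_ppm)))
    stop_invalid("non-finite shift_ppm in peak list")
  x$residue_index <- as.integer(x$residue_index)
  if (any(is.na(x$residue_index) | x$residue_index < 1L))
    stop_invalid("residue_index must be a positive integer")
  state <- if ("state" %in% names(x)) x$state else ""
  keyd <- paste(x$residue_index, x$atom, state)
  if (anyDuplicated(keyd)) {
    d <- keyd[duplicated(keyd)][1]
    stop_invalid("duplicate (residue, atom) entry in peak list: %s", d)
  }
  x
}

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep),
       comments = lines[grepl("^\\s*#", lines)])
}

# "key = value" metadata in comment lines
.parse_meta <- function(comments) {
  m <- regmatches(comments,
                  regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.+?)\\s*$", comments))
  m <- m[lengths(m) == 3L]
  stats::setNames(lapply(m, `[`, 3L), vapply(m, `[`, "", 2L))
}

#' Read a chemical-shift peak list
#'
#' Parses a tab-separated peak list with header columns `residue_index`,
#' `residue_code`, `atom`, `shift_ppm` (and optionally `intensity`,
#' `state`); lines starting with `#` are comments. Malformed rows and
#' duplicate (residue, atom) entries raise errors naming the offending
#' line.
#'
#' @param path file path.
#' @return a validated peak-list data.frame.
#' @seealso [write_peak_list()], [perturbation_profile()]
#' @export
read_peak_list <- function(path) {
  tsv <- .read_tsv_lines(path)
  if (length(tsv$lines) == 0L) stop_io("%s: empty file (no header)", path)
  header <- strsplit(tsv$lines[1], "\t", fixed = TRUE)[[1]]
  missing_c <- setdiff(.peak_cols, header)
  if (length(missing_c))
    stop_io("%s: header lacks column(s): %s", path,
            paste(missing_c, collapse = ", "))
  body <- tsv$lines[-1]
  if (length(body) == 0L) {
    out <- data.frame(residue_index = integer(), residue_code = character(),
                      atom = character(), shift_ppm = numeric())
    return(validate_peak_list(out))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop_io("%s: malformed row at line %d (expected %d fields, got %d)",
            path, tsv$lineno[-1][bad[1]], length(header),
            lengths(fields)[bad[1]])
  mat <- do.call(rbind, fields)
  out <- stats::setNames(as.data.frame(mat, stringsAsFactors = FALSE), header)
  for (col in intersect(c("residue_index", "shift_ppm", "intensity"), header)) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) {
      bad_row <- which(is.na(v))[1]
      stop_io("%s: non-numeric '%s' at line %d", path, col,
              tsv$lineno[-1][bad_row])
    }
    out[[col]] <- v
  }
  validate_peak_list(out)
}

#' Write a chemical-shift peak list
#'
#' @param x a peak-list data.frame.
#' @param path output path.
#' @param comments optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(x, path, comments = character()) {
  x <- validate_peak_list(x)
  cols <- intersect(c(.peak_cols, "intensity", "state"), names(x))
  fmt_col <- function(col) {
    v <- x[[col]]
    switch(col,
           shift_ppm = sprintf("%.4f", v),
           intensity = .fmt_full(v),
           residue_index = as.character(as.integer(v)),
           as.character(v))
  }
  body <- if (nrow(x)) do.call(paste, c(lapply(cols, fmt_col), sep = "\t"))
          else character()
  writeLines(c(if (length(comments)) paste("#", comments),
               paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a titration table
#'
#' Parses a two-column tab-separated titration table. The first column is
#' either `ratio` (molar ratio `c_B/c_A`) or a unit-tagged concentration
#' `c_B_M`/`c_B_mM`/`c_B_uM`/`c_B_nM` (converted to mol/L); the second is
#' `intensity` (fluorescence) or `normalized_shift` (NMR). The total
#' protein concentration is read from a `# c_A_M = <value>` metadata
#' comment (or `# c_A = <value with unit>`); an optional
#' `# temperature = ...` comment is carried along. Non-monotone
#' concentration columns are rejected.
#'
#' @param path file path.
#' @return a [fluorescence_curve()] or [normalized_shift_series()],
#'   depending on the observable column.
#' @seealso [write_titration_table()]
#' @export
read_titration_table <- function(path) {
  tsv <- .read_tsv_lines(path)
  if (length(tsv$lines) < 2L) stop_io("%s: no data rows", path)
  header <- strsplit(tsv$lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) != 2L)
    stop_io("%s: expected a two-column table, got %d columns", path,
            length(header))
  xcol <- header[1]
  ycol <- header[2]
  unit_scale <- c(c_B_M = 1, c_B_mM = 1e-3, c_B_uM = 1e-6, c_B_nM = 1e-9)
  if (!(xcol == "ratio" || xcol %in% names(unit_scale)))
    stop_io("%s: first column must be 'ratio' or c_B_<M|mM|uM|nM>, got '%s'",
            path, xcol)
  if (!ycol %in% c("intensity", "normalized_shift"))
    stop_io("%s: second column must be 'intensity' or 'normalized_shift', got '%s'",
            path, ycol)
  fields <- strsplit(tsv$lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop_io("%s: malformed row at line %d", path, tsv$lineno[-1][bad[1]])
  xv <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  yv <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(xv) || anyNA(yv))
    stop_io("%s: non-numeric value at line %d", path,
            tsv$lineno[-1][which(is.na(xv) | is.na(yv))[1]])
  if (is.unsorted(xv, strictly = TRUE))
    stop_io("%s: concentration/ratio column must be strictly increasing", path)
  meta <- .parse_meta(tsv$comments)
  c_A <- if (!is.null(meta$c_A_M)) as.numeric(meta$c_A_M)
         else if (!is.null(meta$c_A)) parse_concentration(meta$c_A)
         else stop_io("%s: missing '# c_A_M = ...' metadata", path)
  temp <- meta$temperature %||% NA_character_
  if (ycol == "intensity") {
    cb <- xv * if (xcol == "ratio") c_A else unit_scale[[xcol]]
    fluorescence_curve(cb, yv, c_A, temperature_label = temp)
  } else {
    r <- if (xcol == "ratio") xv else xv * unit_scale[[xcol]] / c_A
    normalized_shift_series(r, yv, c_A,
                            averaged = !identical(meta$averaged, "FALSE"))
  }
}

#' Write a titration table
#'
#' Inverse of [read_titration_table()]: writes a [fluorescence_curve()]
#' (columns `c_B_M`, `intensity`) or [normalized_shift_series()] (columns
#' `ratio`, `normalized_shift`) with `# c_A_M` (and temperature) metadata,
#' at full numeric precision so that write-then-read is the identity.
#'
#' @param x a `fluorescence_curve` or `normalized_shift_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(x, path) {
  if (inherits(x, "fluorescence_curve")) {
    meta <- c(sprintf("# c_A_M = %s", .fmt_full(x$c_A)),
              if (!is.na(x$temperature_label))
                sprintf("# temperature = %s", x$temperature_label))
    body <- paste(.fmt_full(x$points$c_B), .fmt_full(x$points$intensity),
                  sep = "\t")
    writeLines(c(meta, "c_B_M\tintensity", body), path)
  } else if (inherits(x, "normalized_shift_series")) {
    meta <- c(sprintf("# c_A_M = %s", .fmt_full(x$c_A)),
              sprintf("# averaged = %s", isTRUE(x$averaged)))
    body <- paste(.fmt_full(x$points$ratio),
                  .fmt_full(x$points$normalized_shift), sep = "\t")
    writeLines(c(meta, "ratio\tnormalized_shift", body), path)
  } else {
    stop_invalid("'x' must be a fluorescence_curve or normalized_shift_series")
  }
  invisible(path)
}

#' Write an epitope map as a per-residue TSV
#'
#' Columns: `residue_index`, `residue_code`, `delta_comb`, `status`,
#' `class`, and (when a consensus table is supplied) `in_consensus`.
#' The threshold `sigma0` and the ligand label go into `#` metadata.
#'
#' @param map an `epitope_map` from [classify_residues()].
#' @param path output path.
#' @param consensus optional result of [consensus_epitope()]; its
#'   `in_consensus` column is joined on `residue_index`.
#' @return `path`, invisibly.
#' @export
write_epitope_map <- function(map, path, consensus = NULL) {
  df <- as.data.frame(map)
  if (!is.null(consensus))
    df$in_consensus <- consensus$in_consensus[
      match(df$residue_index, consensus$residue_index)]
  meta <- c(sprintf("# sigma0_ppm = %.4f", attr(map, "sigma0")),
            sprintf("# ligand = %s", attr(map, "ligand_label")))
  cols <- names(df)
  fmt <- function(col) {
    v <- df[[col]]
    if (col == "delta_comb") ifelse(is.na(v), "NA", sprintf("%.4f", v))
    else as.character(v)
  }
  writeLines(c(meta, paste(cols, collapse = "\t"),
               do.call(paste, c(lapply(cols, fmt), sep = "\t"))), path)
  invisible(path)
}

#' Write a structure-viewer attribute file
#'
#' Two tab-separated columns, `residue_index` and interaction class, with
#' no header -- suitable for per-residue coloring in molecular viewers.
#'
#' @param map an `epitope_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attribute_file <- function(map, path) {
  writeLines(paste(map$residue_index, as.character(map$class), sep = "\t"),
             path)
  invisible(path)
}

#' Write a run manifest
#'
#' Key-value text recording what produced a set of outputs: package
#' version, input paths, the seed, and an md5 digest of the configuration,
#' so any output is reproducible from config + seed alone.
#'
#' @param path output path.
#' @param inputs character vector of input file paths.
#' @param config named list of configuration values.
#' @param seed the RNG seed used (or `NA`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = character(), config = list(),
                           seed = NA) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(deparse(config[order(names(config))]), cfg_file)
  lines <- c(
    sprintf("package = nmrbind %s",
            as.character(utils::packageVersion("nmrbind"))),
    sprintf("r_version = %s", R.version.string),
    sprintf("seed = %s", seed),
    sprintf("config_md5 = %s", unname(tools::md5sum(cfg_file))),
    vapply(names(config), function(k)
      sprintf("config.%s = %s", k, paste(format(config[[k]]), collapse = " ")),
      character(1)),
    if (length(inputs)) sprintf("input = %s", inputs))
  writeLines(lines, path)
  invisible(path)
}

#' Reference dissociation constants from fluorescence quenching
#'
#' Published per-site dissociation constants of the Thermotoga maritima
#' cold shock protein (TmCsp) complexed with homonucleotide heptamers at
#' 303, 323 and 343 K, determined by tryptophan fluorescence quenching
#' under the two-sites-per-heptamer model. These printed values serve as
#' ground truths for parameter-recovery studies and as fixed `K_D` inputs
#' to stoichiometry fits.
#'
#' @return a data.frame with columns `oligonucleotide`, `temperature_K`,
#'   `kd_uM`, `kd_se_uM`, `c_A_M` (protein concentration used, where on
#'   record) and derived `kd_M`, `kd_se_M`.
#' @examples
#' kd_reference()
#' kd_value("dT7", 303) # 4 nM
#' @export
kd_reference <- function() {
  path <- system.file("extdata", "kd_fluorescence_quenching.tsv",
                      package = "nmrbind", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#")
  df$kd_M <- df$kd_uM * 1e-6
  df$kd_se_M <- df$kd_se_uM * 1e-6
  df
}

#' @rdname kd_reference
#' @param oligonucleotide e.g. `"dT7"`, `"rU7"`, `"dA7"`.
#' @param temperature_K 303, 323 or 343.
#' @export
kd_value <- function(oligonucleotide, temperature_K) {
  df <- kd_reference()
  i <- df$oligonucleotide == oligonucleotide &
    df$temperature_K == temperature_K
  if (!any(i))
    stop_invalid("no reference K_D for %s at %s K", oligonucleotide,
                 format(temperature_K))
  df$kd_M[i]
}
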