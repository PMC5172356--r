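#' Read a delimited-text dataset and validate it
#'
#' One entry point for every tabular input the pipeline consumes. Files are
#' header-carrying CSV or TSV (the delimiter is sniffed from the header line,
#' or set via `schema_options$sep`). Long format (one row per observation) is
#' canonical; alternative column names are supplied through
#' `schema_options$columns`, a named list mapping canonical names to the
#' file's names.
#'
#' Canonical columns by kind:
#' \describe{
#'   \item{melt}{`wavelength` (nm), `intensity`, `condition` (K or mol/L),
#'     optional `replicate`. Options: `condition_kind` ("thermal"/"chemical"),
#'     `celsius = TRUE` to convert a Celsius condition axis to K.}
#'   \item{decay}{`residue`, `delay` (s), `intensity`, optional `experiment`
#'     ("T1"/"T2", or via `schema_options$experiment`). Option
#'     `delay_unit = "ms"` converts milliseconds to seconds.}
#'   \item{noe}{`residue`, `i_sat`, `i_eq`, optional `replicate`.}
#'   \item{dsc}{`temperature` (K), `heat_capacity` (kJ/K/mol). Options:
#'     `celsius`, `scan_label`, `scan_rate`.}
#'   \item{peaklist}{either canonical `residue`, `h_ppm`, `n_ppm`,
#'     optional `intensity`; or a Sparky-style whitespace table with columns
#'     `Assignment w1 w2 [Height]` (w1 = 15N, w2 = 1H; the residue number is
#'     taken from the digits of the assignment label).}
#' }
#'
#' Unit conversion happens exactly once at read time, so normalization is
#' idempotent: the returned objects always carry K and seconds.
#'
#' @param path file path.
#' @param kind one of `"melt"`, `"decay"`, `"noe"`, `"dsc"`, `"peaklist"`.
#' @param schema_options named list of options, see Details.
#' @return `melt` -> a `melt_series` data.frame; `decay` -> list of
#'   [decay_curve()]; `noe` -> data.frame (residue, replicate, i_sat, i_eq);
#'   `dsc` -> a [dsc_trace()]; `peaklist` -> a [peak_list()].
#' @export
read_dataset <- function(path,
                         kind = c("melt", "decay", "noe", "dsc", "peaklist"),
                         schema_options = list()) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  so <- schema_options
  if (kind == "peaklist") return(read_peaklist(path, so))
  df <- read_table_auto(path, so)
  df <- remap_columns(df, so$columns)
  switch(kind,
    melt = read_melt(df, so),
    decay = read_decay(df, so),
    noe = read_noe(df, so),
    dsc = read_dsc(df, so)
  )
}

read_table_auto <- function(path, so) {
  sep <- so$sep
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

remap_columns <- function(df, columns) {
  if (is.null(columns)) return(df)
  for (canon in names(columns)) {
    from <- columns[[canon]]
    if (!from %in% names(df))
      stop("schema error: mapped column not in file: ", from)
    names(df)[names(df) == from] <- canon
  }
  df
}

require_columns <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
}

celsius_to_kelvin <- function(x) x + 273.15

read_melt <- function(df, so) {
  require_columns(df, c("wavelength", "intensity", "condition"))
  if (is.null(df$replicate)) df$replicate <- "r1"
  if (isTRUE(so$celsius)) df$condition <- celsius_to_kelvin(df$condition)
  as_melt_series(df, condition_kind = so$condition_kind %||% "thermal")
}

read_decay <- function(df, so) {
  require_columns(df, c("residue", "delay", "intensity"))
  if (is.null(df$experiment))
    df$experiment <- so$experiment %||% "T1"
  if (identical(so$delay_unit, "ms")) df$delay <- df$delay / 1000
  keys <- split(seq_len(nrow(df)), paste(df$residue, df$experiment))
  lapply(unname(keys), function(i) {
    i <- i[order(df$delay[i])]
    decay_curve(df$residue[i][1], df$delay[i], df$intensity[i],
                experiment = df$experiment[i][1])
  })
}

read_noe <- function(df, so) {
  require_columns(df, c("residue", "i_sat", "i_eq"))
  if (is.null(df$replicate)) df$replicate <- "r1"
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$i_sat[i]) || !is.finite(df$i_eq[i]) || df$i_eq[i] == 0)
      stop(sprintf("validation error in row %d: i_eq must be finite and nonzero", i))
  }
  out <- df[, c("residue", "replicate", "i_sat", "i_eq")]
  out$residue <- as.character(out$residue)
  out$replicate <- as.character(out$replicate)
  out
}

read_dsc <- function(df, so) {
  require_columns(df, c("temperature", "heat_capacity"))
  tt <- df$temperature
  if (isTRUE(so$celsius)) tt <- celsius_to_kelvin(tt)
  dsc_trace(tt, df$heat_capacity,
            scan_label = so$scan_label %||% "first_heat",
            scan_rate = so$scan_rate %||% 1)
}

read_peaklist <- function(path, so) {
  header <- readLines(path, n = 1L)
  if (grepl("Assignment", header)) {
    # Sparky-style whitespace table: Assignment w1 w2 [Height]
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    res <- sub("^[^0-9]*([0-9]+).*$", "\\1", df$Assignment)
    if (any(res == df$Assignment))
      stop("schema error: cannot extract residue numbers from Assignment column")
    height <- if ("Height" %in% names(df)) df$Height else NA_real_
    peak_list(res, h_ppm = df$w2, n_ppm = df$w1, intensity = height)
  } else {
    df <- read_table_auto(path, so)
    df <- remap_columns(df, so$columns)
    require_columns(df, c("residue", "h_ppm", "n_ppm"))
    peak_list(df$residue, df$h_ppm, df$n_ppm,
              intensity = df$intensity %||% NA_real_)
  }
}

#' Write a pipeline result to disk
#'
#' Serializes any stage output coercible to a data.frame as TSV (default) or
#' JSON. TSV files carry `# key: value` header lines recording the package
#' version and, when supplied, the RNG seed and physical constants, so that
#' stochastic results (Monte Carlo errors) are replayable. Numeric values are
#' written with 15 significant digits; `read_results()` restores them to
#' within float formatting.
#'
#' @param results data.frame (or coercible) produced by a pipeline stage.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @param constants optional [spin_constants()] echoed into the header.
#' @param seed optional RNG seed echoed into the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          constants = NULL, seed = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  hdr <- result_header(constants = constants, seed = seed)
  if (format == "json") {
    jsonlite::write_json(list(header = hdr, results = df), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(sprintf("# %s: %s", names(hdr),
                       vapply(hdr, function(x) base::format(x, digits = 15),
                              "")), con)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a result file written by [write_results()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame of results (header lines are skipped).
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path)$results)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  }
}

#' Write a per-residue attribute file for structure-viewer coloring
#'
#' One line per residue: residue number, a space, the value. Non-finite
#' values are omitted (with a message), so profiles containing flagged
#' entries can be written directly. The format is the plain two-column text
#' accepted by common viewers for coloring structures by a scalar, e.g. a
#' J(0) ratio profile.
#'
#' @param profile named numeric vector (names = residue numbers) or
#'   data.frame with columns `residue` and `value`.
#' @param path output file path.
#' @return number of lines written, invisibly.
#' @export
write_residue_attributes <- function(profile, path) {
  if (is.data.frame(profile)) {
    res <- profile$residue
    val <- profile$value
  } else {
    res <- names(profile)
    val <- as.vector(profile)
  }
  if (length(val) < 1L) stop("validation error: profile has no residues")
  if (!is.numeric(val)) stop("validation error: attribute values must be numeric")
  keep <- is.finite(val)
  if (any(!keep))
    message(sum(!keep), " non-finite value(s) omitted from attribute file")
  lines <- sprintf("%s %.10g", res[keep], val[keep])
  writeLines(lines, path)
  invisible(length(lines))
}

#' Load a YAML analysis configuration
#'
#' A single structured file carries the field strength, physical constants,
#' RNG seed and fit options, so that stochastic steps are reproducible.
#' Values absent from the file fall back to [default_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return nested list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() {
  list(
    seed = 1L,
    constants = list(field_mhz = 600.13, gamma_h = 2.6752218744e8,
                     gamma_n = -2.7116e7, r_nh = 1.02, delta_sigma = -172),
    fit = list(mc_iterations = 500L, welch = FALSE),
    noise = list(melt_sd = 0.03, relax_fraction = 0.02, dsc_sd = 0)
  )
}
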