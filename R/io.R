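FORMAT_VERSION <- "gshmrs-spectra v1"

fmt_g <- function(x) sprintf("%.17g", x)

#' Write and read the plain-text spectral exchange format
#'
#' A self-describing text container for lists of FIDs: a version line, then
#' per transient a header (acquisition metadata, provenance, processing
#' history) followed by one `re im` line per complex sample printed with 17
#' significant digits, so `read_spectra(write_spectra(x))` round-trips
#' bit-exactly. Malformed headers or truncated bodies raise a parse error
#' naming the offending field.
#'
#' @param fids A list of `mrs_fid`s (a single FID is wrapped).
#' @param path File path.
#' @return `write_spectra()` returns `path` invisibly; `read_spectra()`
#'   returns a list of `mrs_fid`s.
#' @export
write_spectra <- function(fids, path) {
  if (inherits(fids, "mrs_fid")) fids <- list(fids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#", FORMAT_VERSION),
               paste0("#n_transients: ", length(fids))), con)
  for (f in fids) {
    a <- f$acq
    writeLines(c(
      "#transient",
      sprintf("#acq: tr_ms=%s te_ms=%s n_points=%d sw_hz=%s n_averages=%d f0_mhz=%s ref_ppm=%s",
              fmt_g(a$tr_ms), fmt_g(a$te_ms), a$n_points, fmt_g(a$sw_hz),
              a$n_averages, fmt_g(a$f0_mhz), fmt_g(a$ref_ppm)),
      paste0("#provenance: ", f$provenance),
      paste0("#history: ", paste(f$history, collapse = "|")),
      paste0("#n_samples: ", length(f$samples))
    ), con)
    writeLines(paste(fmt_g(Re(f$samples)), fmt_g(Im(f$samples))), con)
  }
  invisible(path)
}

parse_error <- function(field, detail = "") {
  abort(paste0("Spectral file parse error in field `", field, "`. ", detail),
        class = "gshmrs_parse_error")
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != paste0("#", FORMAT_VERSION)) {
    parse_error("version", "Unrecognized or missing version line.")
  }
  nt <- suppressWarnings(as.integer(sub("#n_transients: ", "", lines[2], fixed = TRUE)))
  if (is.na(nt)) parse_error("n_transients")
  pos <- 3
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    if (pos > length(lines) || lines[pos] != "#transient") parse_error("transient")
    acq_line <- lines[pos + 1]
    if (!startsWith(acq_line, "#acq: ")) parse_error("acq")
    kv <- strsplit(sub("#acq: ", "", acq_line, fixed = TRUE), " ")[[1]]
    vals <- setNames(
      as.numeric(sub("^[a-z0-9_]+=", "", kv)),
      sub("=.*$", "", kv))
    if (any(is.na(vals))) parse_error("acq", "Non-numeric value.")
    prov_line <- lines[pos + 2]
    if (!startsWith(prov_line, "#provenance: ")) parse_error("provenance")
    hist_line <- lines[pos + 3]
    if (!startsWith(hist_line, "#history: ")) parse_error("history")
    ns_line <- lines[pos + 4]
    if (!startsWith(ns_line, "#n_samples: ")) parse_error("n_samples")
    ns <- suppressWarnings(as.integer(sub("#n_samples: ", "", ns_line, fixed = TRUE)))
    if (is.na(ns)) parse_error("n_samples")
    body <- lines[pos + 4 + seq_len(ns)]
    if (length(body) < ns || anyNA(body)) {
      parse_error("samples", sprintf("Expected %d sample lines.", ns))
    }
    parts <- strsplit(body, " ", fixed = TRUE)
    if (any(lengths(parts) != 2)) parse_error("samples", "Malformed sample line.")
    re <- as.numeric(vapply(parts, `[`, "", 1))
    im <- as.numeric(vapply(parts, `[`, "", 2))
    if (anyNA(re) || anyNA(im)) parse_error("samples", "Non-numeric sample.")
    acq <- acq_params(vals[["tr_ms"]], vals[["te_ms"]], vals[["n_points"]],
                      vals[["sw_hz"]], vals[["n_averages"]], vals[["f0_mhz"]],
                      vals[["ref_ppm"]])
    hist <- sub("#history: ", "", hist_line, fixed = TRUE)
    out[[k]] <- new_fid(complex(real = re, imaginary = im), acq,
                        sub("#provenance: ", "", prov_line, fixed = TRUE),
                        if (nzchar(hist)) strsplit(hist, "|", fixed = TRUE)[[1]]
                        else character())
    pos <- pos + 5 + ns
  }
  out
}

#' Write a delimited results table
#'
#' Tab-separated text with a header; floating point columns printed at 6
#' significant digits.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(x, path) {
  y <- as.data.frame(x)
  for (j in seq_along(y)) {
    if (is.numeric(y[[j]])) y[[j]] <- sprintf("%.6g", y[[j]])
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns a validated `pipeline_config` (unknown
#'   keys are rejected).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
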