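# Pipeline configuration: every tunable default of the modelling pipeline in
# one serializable record (plain "key = value" text).

#' Default pipeline configuration
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_loop_length = 12L,      # database loop filling cap (residues)
    candidates_per_gap = 20L,   # loop candidates scored per gap
    dist_bin = 1.0,             # FragDB distance bin (Angstrom)
    angle_bin = 20,             # FragDB angle bin (degrees)
    max_pairwise_rmsd = 1.0,    # FragDB redundancy threshold (Angstrom)
    frag_lengths = 3:14,        # indexed fragment lengths
    extra_bins = 1L,            # FragDB query half-width (bins)
    max_extra_bins = 4L,        # widen the query until candidates appear
    ccd_tol = 0.1,              # CCD anchor RMSD tolerance (Angstrom)
    ccd_max_iter = 200L,
    weights = c(cbeta = 1, cb_packing = 1, clash = 1, hbond = 1,
                torsion = 1, reduced = 1, stem_rmsd = 1),
    mc_steps = 1000L,           # Monte Carlo fallback steps per gap
    mc_T0 = 100,                # initial temperature (score units)
    mc_cool = 0.92,             # geometric cooling per sweep
    mc_ccd_iter = 30L,          # CCD iterations inside MC steps
    terminal_max = 10L,         # longest modelled terminal overhang
    regularize_iter = 200L,
    rotamer_mode = "FRM",
    rotamer_coverage = 0.98,
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as plain text
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `write_config`: invisibly `path`; `read_config`: a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  out <- character(0)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.null(names(v)) && length(v) > 1) {
      val <- paste(paste0(names(v), ":", v), collapse = " ")
    } else {
      val <- paste(v, collapse = " ")
    }
    out <- c(out, paste(nm, "=", val))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  defaults <- pipeline_config()
  cfg <- defaults
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "#")) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    nm <- trimws(kv[1])
    if (!nm %in% names(defaults)) stop("unknown config key: ", nm)
    raw <- trimws(paste(kv[-1], collapse = "="))
    toks <- strsplit(raw, "\\s+")[[1]]
    if (all(grepl(":", toks, fixed = TRUE))) {
      parts <- strsplit(toks, ":", fixed = TRUE)
      v <- vapply(parts, function(p) as.numeric(p[2]), 0)
      names(v) <- vapply(parts, `[[`, "", 1)
    } else if (nm == "rotamer_mode") {
      v <- toks
    } else {
      v <- suppressWarnings(as.numeric(toks))
      if (any(is.na(v))) stop("bad value for config key ", nm)
      if (all(v == round(v)) && is.integer(defaults[[nm]])) {
        v <- as.integer(v)
      }
      if (nm == "frag_lengths" && length(v) == 2) v <- v[1]:v[2]
    }
    cfg[[nm]] <- v
  }
  cfg
}
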