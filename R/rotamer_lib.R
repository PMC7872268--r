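# Rotamer libraries: backbone-dependent (10-degree phi/psi grid, the
# Dunbrack 2010 bbdep text dialect is readable) or backbone-independent.
# Entries per key are kept sorted by decreasing probability and renormalized
# to sum to 1.

lib_key <- function(aa, phi_deg = NULL, psi_deg = NULL, bin_deg = 10) {
  if (is.null(phi_deg)) return(aa)
  wrap <- function(x) {
    b <- round(x / bin_deg) * bin_deg
    ((b + 180) %% 360) - 180
  }
  paste(aa, wrap(phi_deg), wrap(psi_deg), sep = "|")
}

new_rotamer_library <- function(entries, backbone_dependent, bin_deg = 10) {
  for (k in names(entries)) {
    es <- entries[[k]]
    p <- vapply(es, `[[`, 0, "probability")
    es <- es[order(-p)]
    p <- sort(p, decreasing = TRUE)
    tot <- sum(p)
    if (tot <= 0) stop("non-positive probability mass for key ", k)
    for (i in seq_along(es)) es[[i]]$probability <- p[i] / tot
    entries[[k]] <- es
  }
  structure(list(entries = entries, backbone_dependent = backbone_dependent,
                 bin_deg = bin_deg),
            class = "rotamer_library")
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat("<rotamer_library> ", length(x$entries), " keys (",
      if (x$backbone_dependent) "backbone-dependent" else
        "backbone-independent", ")\n", sep = "")
  invisible(x)
}

#' Read a backbone-dependent rotamer library
#'
#' Plain-text table dialect: comment lines start with `#`; data lines carry
#' either 17 whitespace-separated fields (aa, phi, psi, count, r1..r4,
#' probability, 4 chi means, 4 chi sigmas -- the Dunbrack 2010 bbdep layout)
#' or 13 fields (without r1..r4). Bins are indexed on a 10-degree grid and
#' probabilities renormalized per (aa, phi, psi) key.
#'
#' @param path file path.
#' @return a `rotamer_library`.
#' @export
read_bbdep_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  for (ln_no in seq_along(lines)) {
    ln <- trimws(lines[[ln_no]])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (!length(f) %in% c(13L, 17L)) {
      stop("malformed rotamer library line ", ln_no, ": expected 13 or 17 ",
           "fields, got ", length(f))
    }
    aa3 <- toupper(f[1])
    if (!aa3 %in% names(AA1)) {
      stop("malformed rotamer library line ", ln_no, ": unknown amino acid '",
           f[1], "'")
    }
    aa <- aa_three_to_one(aa3)
    num <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(num))) {
      stop("malformed rotamer library line ", ln_no, ": non-numeric field")
    }
    base <- if (length(f) == 17L) 8L else 4L  # index after count (+ r1..r4)
    prob <- num[base]
    chis <- num[(base + 1):(base + 4)]
    sigs <- num[(base + 5):(base + 8)]
    nch <- n_chi(aa)
    key <- lib_key(aa, num[1], num[2])
    entry <- list(probability = prob, chi = chis[seq_len(nch)],
                  sigma = sigs[seq_len(nch)])
    entries[[key]] <- c(entries[[key]], list(entry))
  }
  if (length(entries) == 0) stop("empty rotamer library")
  new_rotamer_library(entries, backbone_dependent = TRUE)
}

#' Write a rotamer library in the 13-field text dialect
#' @param lib a `rotamer_library` (backbone-dependent).
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_rotamer_library <- function(lib, path) {
  out <- c("# rotamer library (aa phi psi count prob chi1-4 sig1-4)")
  for (key in names(lib$entries)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    aa3 <- aa_one_to_three(parts[1])
    phi <- if (length(parts) > 1) parts[2] else "0"
    psi <- if (length(parts) > 1) parts[3] else "0"
    for (e in lib$entries[[key]]) {
      chi4 <- rep(0, 4)
      sig4 <- rep(10, 4)
      if (length(e$chi) > 0) chi4[seq_along(e$chi)] <- e$chi
      if (length(e$sigma) > 0) sig4[seq_along(e$sigma)] <- e$sigma
      out <- c(out, paste(aa3, phi, psi, 1,
                          sprintf("%.8g", e$probability),
                          paste(sprintf("%.8g", chi4), collapse = " "),
                          paste(sprintf("%.8g", sig4), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

lib_entries_for <- function(lib, aa, phi_deg, psi_deg) {
  if (!lib$backbone_dependent) {
    es <- lib$entries[[aa]]
    if (is.null(es)) stop("no library entries for ", aa)
    return(es)
  }
  if (!is.null(phi_deg) && !is.na(phi_deg) && !is.na(psi_deg)) {
    es <- lib$entries[[lib_key(aa, phi_deg, psi_deg, lib$bin_deg)]]
    if (!is.null(es)) return(es)
  }
  # terminus / missing bin: pool all entries of this amino acid
  keys <- grep(paste0("^", aa, "(\\||$)"), names(lib$entries), value = TRUE)
  if (length(keys) == 0) stop("no library entries for ", aa)
  pooled <- do.call(c, lib$entries[keys])
  p <- vapply(pooled, `[[`, 0, "probability")
  pooled <- pooled[order(-p)]
  tot <- sum(p)
  for (i in seq_along(pooled)) {
    pooled[[i]]$probability <- pooled[[i]]$probability / tot
  }
  pooled
}

#' Extract a rotamer group for one residue
#'
#' Takes the smallest prefix of the probability-sorted library entries whose
#' cumulative probability reaches `coverage`, and builds rigid (RRM) or
#' flexible (FRM) rotamers in the residue's backbone frame.
#'
#' @param lib a `rotamer_library`.
#' @param aa one-letter code.
#' @param phi,psi backbone torsions in radians (NA at termini: falls back to
#'   the pooled backbone-independent entries).
#' @param frame backbone frame (list `n`, `ca`, `c`, optional `cb`).
#' @param mode `"RRM"` or `"FRM"`.
#' @param coverage cumulative probability mass to cover (default 0.98).
#' @param res_id residue index for frame exclusions.
#' @param K probability-to-energy scale.
#' @return list of `rotamer` (RRM) or `flexible_rotamer` (FRM) objects.
#' @export
get_rotamer_group <- function(lib, aa, phi, psi, frame, mode = "RRM",
                              coverage = 0.98, res_id = NA_integer_, K = 1) {
  mode <- match.arg(mode, c("RRM", "FRM"))
  aa <- toupper(aa)
  if (aa == "G") stop("glycine has no rotamers")
  if (aa == "A") {
    return(list(build_rotamer("A", frame, numeric(0), 1, res_id, K)))
  }
  phi_deg <- if (is.na(phi)) NA else phi * 180 / pi
  psi_deg <- if (is.na(psi)) NA else psi * 180 / pi
  es <- lib_entries_for(lib, aa, phi_deg, psi_deg)
  p <- cumsum(vapply(es, `[[`, 0, "probability"))
  n_keep <- which(p >= coverage - 1e-9)[1]
  if (is.na(n_keep)) n_keep <- length(es)
  es <- es[seq_len(n_keep)]
  lapply(es, function(e) {
    if (mode == "RRM") {
      build_rotamer(aa, frame, e$chi, e$probability, res_id, K)
    } else {
      build_flexible_rotamer(aa, frame, e$chi, e$sigma, e$probability,
                             res_id, K)
    }
  })
}
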