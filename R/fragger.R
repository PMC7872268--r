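# Fragger: sliding-window fragment search over a StructureDB, scoring each
# window by a linear combination of sequence similarity (mean BLOSUM62),
# secondary-structure agreement and torsion-angle probability under trained
# torsion tables. Higher scores are better; the best k windows are returned.

#' Sliding-window fragment search
#'
#' @param db a `structure_db`.
#' @param target_seq one-letter target sequence; its length sets the window.
#' @param target_ss optional target secondary-structure string over
#'   `{H, E, C}` of the same length; when absent the ss term contributes 0.
#' @param weights named numeric vector with any of `sequence`, `ss`,
#'   `torsion`; missing names default to 0.
#' @param k number of fragments to return.
#' @param torsion_pot optional `torsion_potential` (see
#'   [train_potentials()]) for the torsion term; when absent that term is 0.
#' @return data.frame with columns `chain_index`, `offset` (0-based),
#'   `score`, sorted by decreasing score (ties by chain, then offset),
#'   truncated to `k` rows.
#' @export
fragger_search <- function(db, target_seq, target_ss = NULL,
                           weights = c(sequence = 1, ss = 1, torsion = 1),
                           k = 10L, torsion_pot = NULL) {
  stopifnot(inherits(db, "structure_db"), k >= 1)
  w <- c(sequence = 0, ss = 0, torsion = 0)
  w[names(weights)] <- weights
  tchars <- strsplit(toupper(target_seq), "")[[1]]
  wlen <- length(tchars)
  ss_chars <- if (!is.null(target_ss)) strsplit(target_ss, "")[[1]] else NULL
  if (!is.null(ss_chars) && length(ss_chars) != wlen) {
    stop("target_ss length does not match target_seq")
  }

  rows <- list()
  for (ci in seq_along(db$chains)) {
    ch <- db$chains[[ci]]
    L <- nchar(ch$sequence)
    if (L < wlen) next
    cseq <- strsplit(ch$sequence, "")[[1]]
    css <- strsplit(ch$ss, "")[[1]]
    for (off in 0:(L - wlen)) {
      idx <- (off + 1):(off + wlen)
      sc_seq <- mean(vapply(seq_len(wlen), function(j) {
        a <- tchars[j]
        b <- cseq[idx[j]]
        if (a %in% rownames(blosum62) && b %in% rownames(blosum62)) {
          blosum62[a, b]
        } else 0
      }, 0))
      sc_ss <- if (is.null(ss_chars)) 0 else mean(ss_chars == css[idx])
      sc_tor <- 0
      if (!is.null(torsion_pot) && w[["torsion"]] != 0) {
        lp <- vapply(seq_len(wlen), function(j) {
          i <- idx[j]
          if (is.na(ch$phi[i]) || is.na(ch$psi[i])) return(NA_real_)
          -torsion_energy(torsion_pot, cseq[i], ch$phi[i], ch$psi[i])
        }, 0)
        lp <- lp[!is.na(lp)]
        sc_tor <- if (length(lp) > 0) mean(lp) else 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain_index = ci, offset = off,
        score = w[["sequence"]] * sc_seq + w[["ss"]] * sc_ss +
          w[["torsion"]] * sc_tor)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chain_index = integer(0), offset = integer(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$chain_index, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}
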