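#' Match quantitative MS1 clusters to MS2 identification clusters
#'
#' Candidate pairs must agree within \code{ppm_tol} parts-per-million on both
#' m/z and neutral mass and within \code{rt_tol_min} minutes on retention
#' time (an absolute-tolerance mode on all three coordinates is available via
#' \code{mode = "absolute"}). Pairs are ranked by the combined normalized
#' distance \code{sqrt((dmz/tol)^2 + (dmass/tol)^2 + (drt/tol)^2)} and matched
#' greedily in ascending order (ties by lowest MS1 then lowest MS2 index), so
#' each cluster on either side is used at most once.
#'
#' @param ms1 feature table (\code{cluster_id}, \code{rt_min}, \code{mz},
#'   \code{mass_da}).
#' @param ms2 identification cluster table (\code{ms2_id}, \code{rt_min},
#'   \code{mz}, \code{mass_da}, optionally \code{accessions},
#'   \code{peptide_sequence}).
#' @param ppm_tol m/z and mass tolerance in ppm (or in the measurement units
#'   under \code{mode = "absolute"}).
#' @param rt_tol_min retention-time tolerance in minutes.
#' @param mode \code{"ppm"} (relative m/z and mass tolerances) or
#'   \code{"absolute"}.
#' @return a \code{match_result} list: \code{pairs} (data.frame
#'   \code{ms1_cluster_id}, \code{ms2_id}, \code{delta_ppm_mz},
#'   \code{delta_ppm_mass}, \code{delta_rt_min}, \code{distance}),
#'   \code{unmatched_ms1}, \code{n_ms1}, \code{n_matched},
#'   \code{match_rate_percent}.
#' @export
match_clusters <- function(ms1, ms2, ppm_tol = 20, rt_tol_min = 1.0,
                           mode = c("ppm", "absolute")) {
  mode <- match.arg(mode)
  n1 <- nrow(ms1)
  if (is.null(ms2) || nrow(ms2) == 0) {
    return(structure(list(pairs = data.frame(), unmatched_ms1 = ms1$cluster_id,
                          n_ms1 = n1, n_matched = 0L,
                          match_rate_percent = 0L),
                     class = "match_result"))
  }
  o2 <- order(ms2$mz)
  mz2 <- ms2$mz[o2]
  cand <- vector("list", n1)
  for (i in seq_len(n1)) {
    tol_mz <- if (mode == "ppm") ppm_tol * 1e-6 * ms1$mz[i] else ppm_tol
    lo <- findInterval(ms1$mz[i] - tol_mz, mz2) + 1L
    hi <- findInterval(ms1$mz[i] + tol_mz, mz2)
    if (hi < lo) next
    j <- o2[lo:hi]
    dmz <- ms2$mz[j] - ms1$mz[i]
    dmass <- ms2$mass_da[j] - ms1$mass_da[i]
    drt <- ms2$rt_min[j] - ms1$rt_min[i]
    if (mode == "ppm") {
      dmz_u <- dmz / (1e-6 * ms1$mz[i])         # ppm units
      dmass_u <- dmass / (1e-6 * ms1$mass_da[i])
      tol_m <- ppm_tol
    } else {
      dmz_u <- dmz; dmass_u <- dmass; tol_m <- ppm_tol
    }
    ok <- abs(dmz_u) <= tol_m & abs(dmass_u) <= tol_m &
      abs(drt) <= rt_tol_min
    if (!any(ok)) next
    j <- j[ok]
    cand[[i]] <- data.frame(
      i = i, j = j,
      delta_ppm_mz = dmz_u[ok], delta_ppm_mass = dmass_u[ok],
      delta_rt_min = drt[ok],
      distance = sqrt((dmz_u[ok] / tol_m)^2 + (dmass_u[ok] / tol_m)^2 +
                        (drt[ok] / rt_tol_min)^2))
  }
  cand <- do.call(rbind, cand)
  pairs <- data.frame()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$distance, cand$i, cand$j), ]
    used1 <- logical(n1); used2 <- logical(nrow(ms2))
    take <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!used1[cand$i[k]] && !used2[cand$j[k]]) {
        take[k] <- TRUE
        used1[cand$i[k]] <- TRUE
        used2[cand$j[k]] <- TRUE
      }
    }
    sel <- cand[take, ]
    sel <- sel[order(sel$i), ]
    pairs <- data.frame(ms1_cluster_id = ms1$cluster_id[sel$i],
                        ms2_id = ms2$ms2_id[sel$j],
                        delta_ppm_mz = sel$delta_ppm_mz,
                        delta_ppm_mass = sel$delta_ppm_mass,
                        delta_rt_min = sel$delta_rt_min,
                        distance = sel$distance,
                        stringsAsFactors = FALSE)
  }
  n_matched <- nrow(pairs)
  structure(list(pairs = pairs,
                 unmatched_ms1 = setdiff(ms1$cluster_id,
                                         pairs$ms1_cluster_id),
                 n_ms1 = n1, n_matched = n_matched,
                 match_rate_percent = match_rate_percent(n_matched, n1)),
            class = "match_result")
}

#' Rounded match-rate percentage
#'
#' The reporting convention for cluster matching: the percentage of MS1
#' clusters with an accepted MS2 counterpart, rounded to the nearest integer.
#'
#' @param n_matched number of matched MS1 clusters.
#' @param n_total number of MS1 clusters.
#' @return integer percentage.
#' @export
match_rate_percent <- function(n_matched, n_total) .percent(n_matched, n_total)

#' Expand a wide peptide-to-accessions table to long form
#'
#' Identified peptides typically match many homoeologous protein accessions;
#' the long form holds one row per (peptide, accession) pair. Duplicate input
#' pairs are dropped (their count is reported in the \code{"n_deduplicated"}
#' attribute).
#'
#' @param identified data.frame with \code{cluster_id}, \code{accessions}
#'   (semicolon-separated string or list column) and optionally
#'   \code{peptide_sequence}; rows with empty accession lists are skipped.
#' @return a \code{long_identity_table} data.frame: \code{cluster_id},
#'   \code{accession_id}, \code{peptide_sequence}.
#' @export
expand_wide_to_long <- function(identified) {
  acc <- identified$accessions
  if (!is.list(acc)) acc <- strsplit(as.character(acc), ";", fixed = TRUE)
  acc <- lapply(acc, function(a) a[nzchar(a)])
  n_per <- lengths(acc)
  keep <- n_per > 0
  seqs <- if (!is.null(identified$peptide_sequence))
    identified$peptide_sequence else rep(NA_character_, nrow(identified))
  out <- data.frame(
    cluster_id = rep(identified$cluster_id[keep], n_per[keep]),
    accession_id = unlist(acc[keep]),
    peptide_sequence = rep(seqs[keep], n_per[keep]),
    stringsAsFactors = FALSE)
  dup <- duplicated(out[c("cluster_id", "accession_id")])
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_deduplicated") <- n_dup
  class(out) <- c("long_identity_table", "data.frame")
  out
}

#' Summary statistics of a long identity table
#'
#' @param table a [expand_wide_to_long()] result.
#' @return list with \code{peptides_per_accession} and
#'   \code{accessions_per_peptide}, each \code{c(min, mean, max)}.
#' @export
per_accession_stats <- function(table) {
  if (!nrow(table)) stop("empty identity table")
  ppa <- table(table$accession_id)
  app <- table(table$cluster_id)
  list(peptides_per_accession = c(min = min(ppa), mean = mean(ppa),
                                  max = max(ppa)),
       accessions_per_peptide = c(min = min(app), mean = mean(app),
                                  max = max(app)))
}
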