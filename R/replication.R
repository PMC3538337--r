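## In silico replication: compare replication success in a second GWAS for
## genes selected by intramodular connectivity, by gene significance, or by
## discovery P-value.

#' Replication rates by selection metric
#'
#' The gene universe is the set of network genes also scored in the
#' replication GWAS. For \code{k_in}, genes are ranked within each design
#' module by intramodular connectivity and the top fraction is pooled
#' across modules (a pooled global ranking over the design modules is
#' available via \code{kin_mode}). For \code{gs} and \code{gwas_p}, all
#' network genes in the universe are ranked by gene significance or by the
#' best discovery adjusted P. A selected gene replicates when its
#' replication-study unadjusted gene-wide P is at or below the level in any
#' replication trait. Ranking ties break by (metric, then smaller discovery
#' adjusted P, then gene id), so the table is deterministic.
#'
#' @param stats table from \code{\link{computeGeneStats}} including joined
#'   discovery \code{adj_p_<trait>} columns.
#' @param replication_scores \code{\link{genePvalues}} table from the
#'   replication GWAS.
#' @param modules_for_kin module labels whose hubs enter the k_in ranking
#'   (typically the MM-GS-significant modules).
#' @param top_fractions fractions selected (default 0.20, 0.10, 0.05).
#' @param alpha_levels replication significance levels (default 0.05, 0.01,
#'   0.001).
#' @param kin_mode \code{"per_module"} (default) or \code{"pooled"}.
#' @return data.frame: metric, fraction, alpha, n_selected, n_replicated,
#'   rate (percent; NA when no genes are selected).
#' @export
replicationRates <- function(stats, replication_scores,
                             modules_for_kin,
                             top_fractions = c(0.20, 0.10, 0.05),
                             alpha_levels = c(0.05, 0.01, 0.001),
                             kin_mode = c("per_module", "pooled")) {
  kin_mode <- match.arg(kin_mode)
  stopifnot(all(top_fractions > 0 & top_fractions <= 1),
            all(alpha_levels > 0 & alpha_levels <= 1))
  ucols <- grep("^unadj_p_", names(replication_scores), value = TRUE)
  if (!length(ucols)) stop("replication scores carry no unadjusted P columns")
  uni <- stats[stats$gene_id %in% replication_scores$gene_id, , drop = FALSE]
  if (!nrow(uni)) stop("no network genes are annotated in the replication study")
  rep_best <- do.call(pmin, replication_scores[ucols])
  names(rep_best) <- replication_scores$gene_id

  acols <- grep("^adj_p_", names(uni), value = TRUE)
  disc_p <- if (length(acols)) do.call(pmin, uni[acols]) else rep(1, nrow(uni))
  disc_p[is.na(disc_p)] <- 1

  selections <- list()
  for (frac in top_fractions) {
    # k_in: per design module (or pooled over them)
    kin_stats <- uni[uni$module %in% modules_for_kin, , drop = FALSE]
    kin_disc <- disc_p[uni$module %in% modules_for_kin]
    if (kin_mode == "per_module") {
      sel <- character()
      for (md in modules_for_kin) {
        rows <- which(kin_stats$module == md)
        if (!length(rows)) next
        o <- rows[order(-kin_stats$k_in[rows], kin_disc[rows],
                        kin_stats$gene_id[rows])]
        sel <- c(sel, kin_stats$gene_id[o][seq_len(ceiling(frac * length(rows)))])
      }
    } else {
      o <- order(-kin_stats$k_in, kin_disc, kin_stats$gene_id)
      sel <- kin_stats$gene_id[o][seq_len(ceiling(frac * nrow(kin_stats)))]
    }
    selections[[paste("k_in", frac)]] <- unique(sel)

    o <- order(-uni$gs, disc_p, uni$gene_id)
    selections[[paste("gs", frac)]] <-
      uni$gene_id[o][seq_len(ceiling(frac * nrow(uni)))]

    o <- order(disc_p, uni$gene_id)
    selections[[paste("gwas_p", frac)]] <-
      uni$gene_id[o][seq_len(ceiling(frac * nrow(uni)))]
  }

  rows <- list()
  for (frac in top_fractions) for (metric in c("k_in", "gs", "gwas_p")) {
    sel <- selections[[paste(metric, frac)]]
    for (alpha in alpha_levels) {
      n_rep <- sum(rep_best[sel] <= alpha, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, fraction = frac, alpha = alpha,
        n_selected = length(sel), n_replicated = n_rep,
        rate = if (length(sel)) 100 * n_rep / length(sel) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
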