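#' Colocalization priors
#'
#' Per-variant prior probabilities for the five-configuration
#' colocalization model: association with trait 1 only (`p1`), trait 2 only
#' (`p2`), and with both through one shared variant (`p12`), plus the grid
#' of prior effect-size variances averaged over in the approximate Bayes
#' factor.
#'
#' @param p1,p2,p12 per-variant priors, `0 < p12 <= min(p1, p2) < 1`.
#' @param w_grid positive prior variances of the standardized effect.
#' @return a `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w_grid = c(0.01, 0.1, 0.5)) {
  if (!(p12 > 0 && p12 <= min(p1, p2) && max(p1, p2) < 1))
    stop("priors must satisfy 0 < p12 <= min(p1, p2) < 1")
  if (any(w_grid <= 0)) stop("w_grid values must be positive")
  structure(list(p1 = p1, p2 = p2, p12 = p12, w_grid = w_grid),
            class = "coloc_priors")
}

#' Wakefield approximate log Bayes factor
#'
#' For one variant with effect estimate `beta` and standard error `se`, the
#' approximate Bayes factor against the null under a `N(0, W)` effect prior
#' is `log BF = 0.5 * log(V / (V + W)) + (z^2 / 2) * W / (V + W)` with
#' `V = se^2`, `z = beta / se`. The returned value is the log of the
#' arithmetic mean of the BFs over `w_grid`, evaluated by log-sum-exp.
#' Vectorized over `beta`/`se`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s) (> 0).
#' @param w_grid prior variance grid.
#' @return log Bayes factor(s).
#' @export
wakefield_log_abf <- function(beta, se, w_grid = c(0.01, 0.1, 0.5)) {
  if (any(se <= 0)) stop("se must be positive")
  V <- se^2
  z2 <- (beta / se)^2
  lbf <- sapply(w_grid, function(W)
    0.5 * log(V / (V + W)) + (z2 / 2) * (W / (V + W)))
  lbf <- matrix(lbf, nrow = length(beta))
  apply(lbf, 1, logsumexp) - log(length(w_grid))
}

#' Bayesian colocalization of two association signals in one region
#'
#' Enumerates the five causal configurations of the single-shared-variant
#' colocalization model over the variants common to both statistic sets:
#' no association, trait-1 only, trait-2 only, two distinct causal
#' variants, one shared causal variant. With per-variant log approximate
#' Bayes factors `L1, L2`, the un-normalized configuration scores are
#' `S0 = 1`, `S1 = p1 * sum(BF1)`, `S2 = p2 * sum(BF2)`,
#' `S_shared = p12 * sum(BF1 * BF2)` and
#' `S_distinct = p1 * p2 * (sum(BF1) * sum(BF2) - sum(BF1 * BF2))`,
#' all evaluated in log space. The shared-variant posterior is the decision
#' statistic (the PP3/PPA3 of pairwise GWAS colocalization).
#'
#' @param stats1,stats2 data.frames with `variant_id`, `beta`, `se`
#'   (optionally `ref`, `alt`, `maf` for harmonization), restricted to the
#'   locus window.
#' @param priors a [coloc_priors()] object.
#' @param pp_threshold shared-posterior decision threshold.
#' @return a `coloc_result` list: `pp` (named posterior vector summing to
#'   1), `colocalized`, `n_variants`, `lead1`, `lead2`.
#' @export
colocalize_region <- function(stats1, stats2, priors = coloc_priors(),
                              pp_threshold = 0.98) {
  m <- harmonize_stats(stats1, stats2)
  if (nrow(m) < 2L) stop("fewer than 2 shared variants in the region")
  l1 <- wakefield_log_abf(m$beta1, m$se1, priors$w_grid)
  l2 <- wakefield_log_abf(m$beta2, m$se2, priors$w_grid)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  logS <- c(
    null = 0,
    trait1_only = log(priors$p1) + ls1,
    trait2_only = log(priors$p2) + ls2,
    two_distinct = log(priors$p1) + log(priors$p2) +
      logdiffexp(ls1 + ls2, ls12),
    shared = log(priors$p12) + ls12
  )
  if (!is.finite(logS[["two_distinct"]]))
    warning("distinct-configuration score clamped at 0")
  pp <- exp(logS - logsumexp(logS))
  pp <- pp / sum(pp)
  structure(list(
    pp = pp, colocalized = unname(pp["shared"] > pp_threshold),
    n_variants = nrow(m),
    lead1 = m$variant_id[which.max(abs(m$beta1 / m$se1))],
    lead2 = m$variant_id[which.max(abs(m$beta2 / m$se2))]
  ), class = "coloc_result")
}

# intersect two stat sets on shared variants, flipping beta for swapped
# ref/alt and dropping strand-ambiguous high-MAF variants when alleles are
# annotated
harmonize_stats <- function(stats1, stats2) {
  s1 <- as.data.frame(stats1)[, intersect(c("variant_id", "beta", "se", "ref", "alt", "maf"), names(stats1))]
  s2 <- as.data.frame(stats2)[, intersect(c("variant_id", "beta", "se", "ref", "alt", "maf"), names(stats2))]
  m <- merge(s1, s2, by = "variant_id", suffixes = c("1", "2"))
  if (all(c("ref1", "alt1", "ref2", "alt2") %in% names(m))) {
    same <- m$ref1 == m$ref2 & m$alt1 == m$alt2
    swapped <- m$ref1 == m$alt2 & m$alt1 == m$ref2
    m$beta2[swapped] <- -m$beta2[swapped]
    ambiguous <- paste0(m$ref1, m$alt1) %in% c("AT", "TA", "CG", "GC")
    if ("maf1" %in% names(m)) ambiguous <- ambiguous & m$maf1 > 0.4
    m <- m[(same | swapped) & !ambiguous, , drop = FALSE]
  }
  m
}

#' Select candidate colocalization loci by the three-condition filter
#'
#' Iterates disease variants in ascending p-value while `p < p_disease_max`.
#' Each surviving lead defines a window of `lead position +/- half_window`;
#' disease leads falling inside a window already emitted for some locus are
#' skipped (greedy masking). Within a window, a QTL feature qualifies when
#' (1) the disease lead has `p < p_disease_max`, (2) the feature's lead
#' p-value inside the window is `< p_qtl_max`, and (3) at least one variant
#' other than the disease lead itself simultaneously has QTL chi-square
#' `>= overlap_frac x` the feature's lead chi-square in the window and
#' disease chi-square `>= overlap_frac x` the disease lead's chi-square
#' (the disease lead is excluded because it satisfies its own condition
#' trivially; overlap must be corroborated elsewhere in the locus). One
#' locus row is emitted per qualifying (disease lead, feature) pair.
#'
#' @param disease a `sumstats` data.frame.
#' @param qtl a `cis_results` data.frame (one or many features).
#' @param p_disease_max,p_qtl_max,overlap_frac,half_window filter settings.
#' @return data.frame of candidate loci (possibly 0 rows): locus_id,
#'   lead_variant, lead_pos, lead_p, window_start, window_end, feature_id,
#'   qtl_lead_variant, qtl_lead_p.
#' @export
select_candidate_loci <- function(disease, qtl, p_disease_max = 1e-6,
                                  p_qtl_max = 1e-4, overlap_frac = 0.8,
                                  half_window = 100000) {
  empty <- data.frame(locus_id = character(), lead_variant = character(),
                      lead_pos = integer(), lead_p = numeric(),
                      window_start = numeric(), window_end = numeric(),
                      feature_id = character(),
                      qtl_lead_variant = character(),
                      qtl_lead_p = numeric(), stringsAsFactors = FALSE)
  if (nrow(disease) == 0L || nrow(qtl) == 0L) return(empty)
  dis <- as.data.frame(disease)[order(disease$p, disease$pos), ]
  emitted <- list()
  out <- list()
  for (i in seq_len(nrow(dis))) {
    if (dis$p[i] >= p_disease_max) break
    lead_pos <- dis$pos[i]
    masked <- any(vapply(emitted, function(w)
      lead_pos >= w[1] && lead_pos <= w[2], logical(1)))
    if (masked) next
    lo <- lead_pos - half_window; hi <- lead_pos + half_window
    dwin <- dis[dis$pos >= lo & dis$pos <= hi, , drop = FALSE]
    # the 0.8x disease reference is the strongest disease variant in the
    # window (normally the iterated lead itself)
    lead_chisq <- max(dwin$chisq)
    lead_id <- dwin$variant_id[which.max(dwin$chisq)]
    qwin <- qtl[qtl$pos >= lo & qtl$pos <= hi, , drop = FALSE]
    if (nrow(qwin) == 0L) next
    any_emitted <- FALSE
    for (f in unique(qwin$feature_id)) {
      qf <- qwin[qwin$feature_id == f, , drop = FALSE]
      q_lead <- which.min(qf$p)
      if (qf$p[q_lead] >= p_qtl_max) next
      shared <- merge(qf[, c("variant_id", "chisq")],
                      dwin[, c("variant_id", "chisq")],
                      by = "variant_id", suffixes = c("_qtl", "_dis"))
      shared <- shared[shared$variant_id != lead_id, , drop = FALSE]
      c3 <- any(shared$chisq_qtl >= overlap_frac * qf$chisq[q_lead] &
                  shared$chisq_dis >= overlap_frac * lead_chisq)
      if (!c3) next
      any_emitted <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        locus_id = sprintf("%s_%s", dis$variant_id[i], f),
        lead_variant = dis$variant_id[i], lead_pos = lead_pos,
        lead_p = dis$p[i], window_start = lo, window_end = hi,
        feature_id = f, qtl_lead_variant = qf$variant_id[q_lead],
        qtl_lead_p = qf$p[q_lead], stringsAsFactors = FALSE
      )
    }
    if (any_emitted) emitted[[length(emitted) + 1L]] <- c(lo, hi)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Classify disease loci by caQTL/eQTL colocalization
#'
#' Labels each locus `both`, `caQTL_only`, `eQTL_only` or `none` according
#' to whether any caQTL / any eQTL colocalization result at the locus
#' passed the shared-posterior threshold. When a second eQTL result set is
#' supplied (meta-analyzed or other-context statistics), also reports which
#' `caQTL_only` loci convert to `both`.
#'
#' @param ca,eq data.frames with `locus_id` and logical `colocalized`
#'   (several rows per locus allowed).
#' @param eq2 optional second eQTL result set, same shape.
#' @return data.frame: locus_id, caqtl, eqtl, label, and (with `eq2`)
#'   eqtl2, converts_to_both.
#' @export
classify_locus_sets <- function(ca, eq, eq2 = NULL) {
  loci <- sort(unique(c(ca$locus_id, eq$locus_id,
                        if (!is.null(eq2)) eq2$locus_id)))
  hit <- function(res, l) {
    if (is.null(res) || nrow(res) == 0L) return(FALSE)
    any(res$colocalized[res$locus_id == l])
  }
  out <- data.frame(locus_id = loci,
                    caqtl = vapply(loci, hit, logical(1), res = ca),
                    eqtl = vapply(loci, hit, logical(1), res = eq),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$label <- ifelse(out$caqtl & out$eqtl, "both",
                      ifelse(out$caqtl, "caQTL_only",
                             ifelse(out$eqtl, "eQTL_only", "none")))
  if (!is.null(eq2)) {
    out$eqtl2 <- vapply(loci, hit, logical(1), res = eq2)
    out$converts_to_both <- out$label == "caQTL_only" & out$eqtl2
  }
  out
}

#' Pair caQTLs with eQTLs by lead-variant LD and colocalization
#'
#' Candidate (peak, gene) pairs must both reach QTL lead
#' `p < p_qtl_max`, their lead variants must be in LD `r^2 >= r2_min`, and —
#' when a disease statistic set is supplied — some disease variant with
#' `p < p_disease_max` must lie inside the locus. Colocalization is then
#' evaluated on the variants within `half_window` of the tested peak, and
#' pairs whose shared posterior exceeds `pp_threshold` are emitted with
#' their peak-to-TSS distance.
#'
#' @param caqtl,eqtl `cis_results` tables for peaks and genes.
#' @param panel the `genotype_panel` used to compute lead-variant LD.
#' @param peaks,genes feature tables (for windows and distances).
#' @param disease optional `sumstats` table gating loci on disease
#'   association.
#' @param r2_min lead-variant LD threshold.
#' @param half_window window around the peak (bp).
#' @param priors a [coloc_priors()] object.
#' @param pp_threshold shared-posterior decision threshold.
#' @param p_qtl_max,p_disease_max association gates.
#' @return data.frame: peak_id, gene_id, distance, lead_r2, pp_shared,
#'   colocalized.
#' @export
pair_caqtl_eqtl <- function(caqtl, eqtl, panel, peaks, genes,
                            disease = NULL, r2_min = 0.8,
                            half_window = 200000,
                            priors = coloc_priors(), pp_threshold = 0.98,
                            p_qtl_max = 1e-4, p_disease_max = 1e-6) {
  ca_leads <- cis_leads(caqtl); e_leads <- cis_leads(eqtl)
  ca_leads <- ca_leads[ca_leads$p < p_qtl_max, , drop = FALSE]
  e_leads <- e_leads[e_leads$p < p_qtl_max, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ca_leads))) {
    pk <- peaks[peaks$id == ca_leads$feature_id[i], , drop = FALSE]
    if (nrow(pk) != 1L) next
    mid <- (pk$start + pk$end) / 2
    lo <- mid - half_window; hi <- mid + half_window
    if (!is.null(disease) &&
        !any(disease$p < p_disease_max & disease$pos >= lo &
               disease$pos <= hi)) next
    for (j in seq_len(nrow(e_leads))) {
      gn <- genes[genes$id == e_leads$feature_id[j], , drop = FALSE]
      if (nrow(gn) != 1L) next
      r2 <- ld_r2(panel, ca_leads$variant_id[i], e_leads$variant_id[j])
      if (is.na(r2) || r2 < r2_min) next
      s1 <- caqtl[caqtl$feature_id == pk$id & caqtl$pos >= lo &
                    caqtl$pos <= hi, , drop = FALSE]
      s2 <- eqtl[eqtl$feature_id == gn$id & eqtl$pos >= lo &
                   eqtl$pos <= hi, , drop = FALSE]
      if (nrow(s1) < 2L || nrow(s2) < 2L) next
      cr <- colocalize_region(s1, s2, priors, pp_threshold)
      if (!cr$colocalized) next
      out[[length(out) + 1L]] <- data.frame(
        peak_id = pk$id, gene_id = gn$id,
        distance = peak_tss_distance(pk, gn),
        lead_r2 = r2, pp_shared = unname(cr$pp["shared"]),
        colocalized = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), lead_r2 = numeric(),
                      pp_shared = numeric(), colocalized = logical()))
  do.call(rbind, out)
}

#' LD r-squared between two panel variants
#' @param panel a `genotype_panel`.
#' @param id1,id2 variant ids.
#' @return squared Pearson correlation of the dosages (`NA` if either
#'   variant is missing or monomorphic).
#' @export
ld_r2 <- function(panel, id1, id2) {
  j1 <- match(id1, panel$variants$id); j2 <- match(id2, panel$variants$id)
  if (is.na(j1) || is.na(j2)) return(NA_real_)
  suppressWarnings(stats::cor(panel$dosages[, j1], panel$dosages[, j2])^2)
}
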