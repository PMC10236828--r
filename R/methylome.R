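#' Site-level differential methylation test
#'
#' Per CpG, OLS regression of the M-value on a two-group indicator plus
#' covariates (age, sex, batch, ...); two-sided p from the t statistic and
#' Benjamini-Hochberg adjusted p (Bonferroni behind `adjust`). With no
#' covariates the statistic equals the equal-variance two-sample t statistic.
#' Constant CpGs get `p = 1` with a warning.
#'
#' @param methylome a [methylation_matrix()].
#' @param groups two-level factor/vector, one per sample.
#' @param covariates optional data frame of numeric covariates.
#' @param contrast label stored in the result (`"risk"` for case-control,
#'   `"response"` for RES vs non-RES).
#' @param adjust multiplicity adjustment, `"BH"` (default) or `"bonferroni"`.
#' @return tibble: `cpg_id`, `contrast`, `effect` (M-value difference,
#'   second level minus first), `se`, `statistic`, `p`, `p_adj`.
#' @export
site_dm_test <- function(methylome, groups, covariates = NULL,
                         contrast = "risk", adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  g <- factor(groups)
  if (nlevels(g) != 2) abort("groups must have exactly two levels")
  if (min(table(g)) < 3) abort("each group needs at least 3 samples")
  M <- beta_to_m(methylome$betas)
  X <- cbind(1, as.integer(g) - 1L,
             covariates_matrix(covariates, nrow(M)))
  const <- apply(M, 2, function(x) sd(x) == 0)
  res <- fast_ols(M, X, term = 2L)
  if (any(const)) {
    warn(sprintf("%d constant CpG(s): p set to 1", sum(const)))
    res$p[const] <- 1
    res$statistic[const] <- 0
  }
  tibble::tibble(
    cpg_id = colnames(M), contrast = contrast,
    effect = res$estimate, se = res$se, statistic = res$statistic,
    p = res$p, p_adj = p.adjust(res$p, method = adjust)
  )
}

#' Seed-and-extend DMR detection with Stouffer-Liptak combination
#'
#' Per chromosome, CpGs with `p < seed_p` seed regions that extend over
#' consecutive sub-threshold CpGs while the gap to the next one is at most
#' `max_gap_bp`; regions with at least `min_cpgs` members are kept. The
#' region p combines member z-scores by the Stouffer-Liptak method under an
#' exponential distance-decay correlation
#' `corr(i, j) = rho0 * exp(-dist_ij / decay_bp)`, and the Sidak-style
#' correction uses `n_tests_effective = floor(n_sites_scanned / region size)`.
#'
#' @param site_results tibble from [site_dm_test()] (or any table with
#'   `cpg_id`, `p`, and optionally `effect`).
#' @param cpg_meta tibble with `cpg_id`, `chrom`, `pos` (and optionally
#'   `gene`), sorted or not; positions must be unique per chromosome.
#' @param seed_p seed/extension p-value threshold.
#' @param max_gap_bp maximum gap between consecutive member CpGs.
#' @param min_cpgs minimum member count.
#' @param rho0,decay_bp distance-decay correlation parameters.
#' @return tibble of class `dmr_result`: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_cpgs`, `combined_p`, `sidak_p`, `direction`, `contrast`,
#'   `genes`, `cpgs` (list column of member ids).
#' @export
dmr_detect <- function(site_results, cpg_meta, seed_p = 0.05,
                       max_gap_bp = 500, min_cpgs = 3,
                       rho0 = 0.5, decay_bp = 500) {
  sr <- dplyr::inner_join(tibble::as_tibble(site_results),
                          dplyr::select(tibble::as_tibble(cpg_meta),
                                        "cpg_id", "chrom", "pos",
                                        dplyr::any_of("gene")),
                          by = "cpg_id")
  n_total <- nrow(sr)
  out <- list()
  for (ch in unique(sr$chrom)) {
    s <- dplyr::arrange(sr[sr$chrom == ch, , drop = FALSE], .data$pos)
    if (is.unsorted(s$pos, strictly = FALSE)) abort("unsorted positions")
    sig <- s$p < seed_p
    # maximal runs of sub-threshold CpGs with inter-CpG gaps <= max_gap_bp
    run_id <- integer(nrow(s))
    cur <- 0L
    for (i in seq_len(nrow(s))) {
      if (!sig[i]) next
      new_run <- cur == 0L ||
        {j <- max(which(run_id == cur)); s$pos[i] - s$pos[j] > max_gap_bp}
      if (new_run) cur <- cur + 1L
      if (cur == 0L) cur <- 1L
      run_id[i] <- cur
    }
    for (r in seq_len(max(cur, 0L))) {
      m <- which(run_id == r)
      if (length(m) < min_cpgs) next
      pos <- s$pos[m]
      D <- abs(outer(pos, pos, "-"))
      Sig <- rho0 * exp(-D / decay_bp)
      diag(Sig) <- 1
      z <- qnorm(s$p[m] / 2, lower.tail = FALSE) *
        sign(s$effect[m] %||% rep(1, length(m)))
      # Stouffer-Liptak on magnitude-signed z, two-sided on the combined z
      zc <- sum(z) / sqrt(sum(Sig))
      combined_p <- 2 * pnorm(abs(zc), lower.tail = FALSE)
      n_eff <- max(1, floor(n_total / length(m)))
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = min(pos), end = max(pos),
        n_cpgs = length(m), combined_p = combined_p,
        sidak_p = 1 - (1 - combined_p)^n_eff,
        direction = sign(mean(s$effect[m] %||% 0)),
        contrast = s$contrast[m][1] %||% NA_character_,
        genes = paste(unique(stats::na.omit(s$gene[m] %||% NA_character_)),
                      collapse = ";"),
        cpgs = list(s$cpg_id[m])
      )
    }
  }
  res <- if (length(out)) purrr::list_rbind(out) else
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   n_cpgs = integer(), combined_p = double(),
                   sidak_p = double(), direction = double(),
                   contrast = character(), genes = character(),
                   cpgs = list())
  class(res) <- c("dmr_result", class(res))
  res
}

#' Epigenome-wide association scan of a continuous outcome
#'
#' Per CpG, OLS regression of the outcome (e.g. the scaled PANSS reduction
#' rate) on the CpG M-value plus covariates; computed by
#' Frisch-Waugh residualization so thousands of sites run in one pass.
#' Sites passing the genome-wide rule (default BH-adjusted p below 1e-8)
#' are flagged.
#'
#' @param methylome a [methylation_matrix()].
#' @param outcome numeric vector, one per sample.
#' @param covariates optional covariate data frame.
#' @param sites optional character vector restricting the scan (e.g. CpGs of
#'   ASM genes).
#' @param signif_p_adj genome-wide threshold on the adjusted p.
#' @return tibble `cpg_id`, `contrast = "response"`, `effect`, `se`,
#'   `statistic`, `p`, `p_adj`, `genome_wide` (logical flag).
#' @export
ewas_scan <- function(methylome, outcome, covariates = NULL, sites = NULL,
                      signif_p_adj = 1e-8) {
  if (length(outcome) < 10) abort("need at least 10 samples")
  if (sd(outcome) == 0) abort("outcome is constant")
  M <- beta_to_m(methylome$betas)
  if (!is.null(sites)) M <- M[, intersect(sites, colnames(M)), drop = FALSE]
  n <- nrow(M)
  cm <- covariates_matrix(covariates, n)
  y_r <- residualize(matrix(outcome), if (ncol(cm)) cm else NULL)[, 1]
  M_r <- residualize(M, if (ncol(cm)) cm else NULL)
  df <- n - 2L - ncol(cm)
  sxx <- colSums(M_r^2)
  ok <- sxx > 0
  b <- colSums(M_r * y_r) / sxx
  rss <- sum(y_r^2) - b^2 * sxx
  se <- sqrt(rss / df / sxx)
  tval <- b / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  p[!ok] <- 1
  p_adj <- p.adjust(p, "BH")
  tibble::tibble(
    cpg_id = colnames(M), contrast = "response",
    effect = unname(ifelse(ok, b, 0)), se = unname(se),
    statistic = unname(ifelse(ok, tval, 0)),
    p = unname(p), p_adj = unname(p_adj),
    genome_wide = unname(p_adj < signif_p_adj)
  )
}

#' Genomic-context enrichment table
#'
#' Cross-tabulates CpG genomic context (promoter features, body, UTRs) by
#' CpG-island relation for a set of records; fractions sum to one.
#'
#' @param records tibble with a `cpg_id` column (site results) or a `cpgs`
#'   list column (DMR records).
#' @param cpg_meta tibble with `cpg_id`, `context`, `island`.
#' @return tibble `context`, `island`, `n`, `fraction`.
#' @export
annotate_cpg_context <- function(records, cpg_meta) {
  ids <- if ("cpgs" %in% names(records)) unique(unlist(records$cpgs))
         else unique(records$cpg_id)
  meta <- tibble::as_tibble(cpg_meta)
  hit <- meta[meta$cpg_id %in% ids, , drop = FALSE]
  tab <- dplyr::count(hit, .data$context, .data$island, name = "n")
  tab$fraction <- tab$n / sum(tab$n)
  tab
}
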