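#' cis-meQTL scan
#'
#' For every cis SNP-CpG pair (distance at most `cis_window_bp`), OLS of the
#' CpG M-value on the SNP dosage plus covariates, computed by residualizing
#' both blocks on the covariates once (Frisch-Waugh) and forming per-pair
#' statistics from cross-products. Pairs whose BH-adjusted p passes
#' `threshold` are flagged as meQTLs. Constant dosage columns are skipped
#' with a warning.
#'
#' @param genotypes a [genotype_matrix()].
#' @param methylome a [methylation_matrix()] on the same samples.
#' @param covariates optional covariate data frame (age, sex, ...).
#' @param cis_window_bp cis window (default 1 Mb).
#' @param threshold adjusted-p threshold flagging a pair as a meQTL
#'   (default 1e-8, the conventional genome-wide rule for dense scans).
#' @return tibble: `snp_id`, `cpg_id`, `beta` (M-value change per effect
#'   allele), `se`, `statistic`, `p`, `p_adj`, `cis`, `is_meqtl`.
#' @export
meqtl_scan <- function(genotypes, methylome, covariates = NULL,
                       cis_window_bp = 1e6, threshold = 1e-8) {
  if (nrow(genotypes$dosages) != nrow(methylome$betas)) {
    abort("genotypes and methylome must cover the same samples")
  }
  n <- nrow(genotypes$dosages)
  if (n < 20) abort("need at least 20 shared samples")
  sm <- genotypes$snp_meta
  cm_meta <- methylome$cpg_meta
  pairs <- dplyr::inner_join(
    dplyr::select(sm, "snp_id", "chrom", snp_pos = "pos"),
    dplyr::select(cm_meta, "cpg_id", "chrom", cpg_pos = "pos"),
    by = "chrom", relationship = "many-to-many"
  ) |> dplyr::filter(abs(.data$snp_pos - .data$cpg_pos) <= cis_window_bp)
  if (nrow(pairs) == 0) {
    warn("no cis SNP-CpG pairs within the window")
    return(tibble::tibble(snp_id = character(), cpg_id = character(),
                          beta = double(), se = double(),
                          statistic = double(), p = double(),
                          p_adj = double(), cis = logical(),
                          is_meqtl = logical()))
  }
  cmx <- covariates_matrix(covariates, n)
  G_r <- residualize(genotypes$dosages, if (ncol(cmx)) cmx else NULL)
  M_r <- residualize(beta_to_m(methylome$betas), if (ncol(cmx)) cmx else NULL)
  gi <- match(pairs$snp_id, colnames(G_r))
  ci <- match(pairs$cpg_id, colnames(M_r))
  sxx <- colSums(G_r^2)[gi]
  syy <- colSums(M_r^2)[ci]
  const <- sxx <= 1e-12
  if (any(const)) {
    warn(sprintf("skipping %d pair(s) with constant dosage", sum(const)))
    pairs <- pairs[!const, , drop = FALSE]
    gi <- gi[!const]; ci <- ci[!const]
    sxx <- sxx[!const]; syy <- syy[!const]
  }
  sxy <- colSums(G_r[, gi, drop = FALSE] * M_r[, ci, drop = FALSE])
  b <- sxy / sxx
  df <- n - 2L - ncol(cmx)
  rss <- syy - b * sxy
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- b / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  p_adj <- p.adjust(p, "BH")
  tibble::tibble(
    snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
    beta = b, se = se, statistic = tval, p = p, p_adj = p_adj,
    cis = TRUE, is_meqtl = p_adj < threshold
  )
}

#' Allele-specific-methylation gene set
#'
#' A gene qualifies when it is implicated jointly by the three inputs. In
#' `"gene"` mode (default) the three conditions may be met by different CpGs
#' of the gene: at least one CpG inside a risk-DMR, at least one inside a
#' RES-DMR, and at least one that is a meQTL target. In `"cpg"` mode a
#' single CpG must satisfy all three.
#'
#' @param meqtls meQTL table from [meqtl_scan()] (rows with `is_meqtl` are
#'   used; a pre-filtered table without the flag is accepted).
#' @param risk_dmrs,res_dmrs [dmr_detect()] outputs for the case-control and
#'   responder contrasts.
#' @param cpg_meta tibble `cpg_id`, `gene` (multiple genes `;`-separated).
#' @param mode `"gene"` or `"cpg"`.
#' @return tibble `gene` plus the qualifying CpG ids per route.
#' @export
asm_gene_set <- function(meqtls, risk_dmrs, res_dmrs, cpg_meta,
                         mode = c("gene", "cpg")) {
  mode <- match.arg(mode)
  mq_cpgs <- if ("is_meqtl" %in% names(meqtls)) {
    unique(meqtls$cpg_id[meqtls$is_meqtl])
  } else unique(meqtls$cpg_id)
  risk_cpgs <- unique(unlist(risk_dmrs$cpgs))
  res_cpgs <- unique(unlist(res_dmrs$cpgs))
  g2c <- tibble::as_tibble(cpg_meta) |>
    dplyr::select("cpg_id", "gene") |>
    tidyr::separate_longer_delim("gene", ";") |>
    dplyr::filter(!is.na(.data$gene), .data$gene != "")
  if (mode == "cpg") {
    qual <- intersect(intersect(mq_cpgs, risk_cpgs), res_cpgs)
    hits <- g2c[g2c$cpg_id %in% qual, , drop = FALSE]
    return(dplyr::summarise(dplyr::group_by(hits, .data$gene),
                            cpgs = list(unique(.data$cpg_id)),
                            .groups = "drop"))
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(g2c, .data$gene),
    meqtl = any(.data$cpg_id %in% mq_cpgs),
    risk = any(.data$cpg_id %in% risk_cpgs),
    res = any(.data$cpg_id %in% res_cpgs),
    cpgs = list(unique(.data$cpg_id)),
    .groups = "drop"
  )
  dplyr::filter(per_gene, .data$meqtl, .data$risk, .data$res) |>
    dplyr::select("gene", "cpgs")
}

#' Promoter-anchored chromatin interaction strength comparison
#'
#' Two-tailed Wilcoxon rank-sum test on per-interaction strengths
#' (`-log10` of the interaction significance) between two conditions; exact
#' null when the combined sample is at most 20 and untied, normal
#' approximation with tie correction otherwise. All-tied inputs yield
#' `p = 1` with a warning.
#'
#' @param strengths_a,strengths_b numeric `-log10` strength vectors for the
#'   two conditions (each at least 3 values).
#' @param gene optional gene label carried into the result.
#' @return tibble `gene`, `n_a`, `n_b`, `median_a`, `median_b`, `statistic`
#'   (rank-sum W), `p`.
#' @export
pai_compare <- function(strengths_a, strengths_b, gene = NA_character_) {
  if (length(strengths_a) < 3 || length(strengths_b) < 3) {
    abort("each condition needs at least 3 interaction strengths")
  }
  all_tied <- length(unique(c(strengths_a, strengths_b))) == 1
  if (all_tied) {
    warn("all interaction strengths tied; p = 1")
    w <- list(statistic = length(strengths_a) * length(strengths_b) / 2,
              p.value = 1)
  } else {
    exact <- (length(strengths_a) + length(strengths_b)) <= 20 &&
      !any(duplicated(c(strengths_a, strengths_b)))
    w <- suppressWarnings(
      wilcox.test(strengths_a, strengths_b, exact = exact, correct = !exact)
    )
  }
  tibble::tibble(gene = gene,
                 n_a = length(strengths_a), n_b = length(strengths_b),
                 median_a = median(strengths_a), median_b = median(strengths_b),
                 statistic = unname(w$statistic), p = w$p.value)
}

#' Refine ASM candidates by colocalization, SMR/HEIDI + PAI, and EWAS
#'
#' Applies the three refinement routes and keeps the union with per-route
#' provenance: COLOC when any region of the gene has `PP4 > 0.8`; PAI when
#' the SMR p passes a 5% FDR across candidate genes, the HEIDI p exceeds
#' 0.01 (no heterogeneity), and the interaction-strength comparison is
#' significant; EWAS when any CpG of the gene passes the genome-wide rule.
#'
#' @param asm_genes tibble from [asm_gene_set()].
#' @param coloc_results tibble with `gene` and `pp4` (one row per region).
#' @param smr_results tibble with `gene`, `p_smr`, `p_heidi`.
#' @param pai_comparisons tibble with `gene`, `p` (from [pai_compare()]).
#' @param ewas_hits tibble from [ewas_scan()] plus a `gene` column.
#' @param pp4_threshold,heidi_threshold,smr_fdr,pai_alpha route parameters.
#' @return tibble `gene`, `coloc`, `pai`, `ewas`, `routes`; genes passing no
#'   route are dropped.
#' @export
refine_candidates <- function(asm_genes, coloc_results = NULL,
                              smr_results = NULL, pai_comparisons = NULL,
                              ewas_hits = NULL,
                              pp4_threshold = 0.8, heidi_threshold = 0.01,
                              smr_fdr = 0.05, pai_alpha = 0.05) {
  genes <- unique(asm_genes$gene)
  if (length(genes) == 0) {
    return(tibble::tibble(gene = character(), coloc = logical(),
                          pai = logical(), ewas = logical(),
                          routes = character()))
  }
  coloc_pass <- rep(FALSE, length(genes))
  if (!is.null(coloc_results) && nrow(coloc_results)) {
    hit <- coloc_results$gene[coloc_results$pp4 > pp4_threshold]
    coloc_pass <- genes %in% hit
  }
  pai_pass <- rep(FALSE, length(genes))
  if (!is.null(smr_results) && nrow(smr_results)) {
    sr <- tibble::as_tibble(smr_results)
    sr$fdr <- p.adjust(sr$p_smr, "BH")
    smr_ok <- sr$gene[sr$fdr < smr_fdr &
                        !is.na(sr$p_heidi) & sr$p_heidi > heidi_threshold]
    pai_ok <- if (!is.null(pai_comparisons) && nrow(pai_comparisons)) {
      pai_comparisons$gene[pai_comparisons$p < pai_alpha]
    } else character()
    pai_pass <- genes %in% intersect(smr_ok, pai_ok)
  }
  ewas_pass <- rep(FALSE, length(genes))
  if (!is.null(ewas_hits) && nrow(ewas_hits)) {
    hit <- ewas_hits$gene[ewas_hits$genome_wide %||% rep(TRUE, nrow(ewas_hits))]
    ewas_pass <- genes %in% hit
  }
  out <- tibble::tibble(gene = genes, coloc = coloc_pass, pai = pai_pass,
                        ewas = ewas_pass)
  out$routes <- purrr::pmap_chr(out[c("coloc", "pai", "ewas")],
                                function(coloc, pai, ewas) {
    paste(c("COLOC", "PAI", "EWAS")[c(coloc, pai, ewas)], collapse = "+")
  })
  dplyr::filter(out, .data$coloc | .data$pai | .data$ewas)
}
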