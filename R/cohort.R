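#' Parameters for the synthetic multi-omic cohort generator
#'
#' The generator emulates the joined WGS + RNA-seq + annotation table of a
#' pan-cancer cohort: per sample a tumor type, p53 mutation status, locus
#' RNA (TPM), locus transduction-bearing RT counts, total RT burden, and
#' sequencing QC covariates. The generative chain is log-linear so that OLS
#' on log2 scales recovers the planted effects: locus RNA is log2-normal
#' with a p53 effect `alpha_true` (log2 units) and tumor-type shifts; locus
#' TRT is Poisson with rate `efficiency_i * run_on_i * RNA_i *
#' exp(tau_prime_true * p53)`; total RT adds a Poisson background.
#'
#' @param n_samples Number of tumor samples.
#' @param tumor_types Character vector of type labels.
#' @param type_props Mixing proportions (sum to 1).
#' @param p53_mut_prob Per-type probability of TP53 alteration.
#' @param n_loci Number of L1 loci.
#' @param baseline_log2 Optional per-locus baseline log2 TPM (drawn
#'   Uniform(-3, 2) when `NULL`).
#' @param dispersion Log2-scale RNA standard deviation.
#' @param type_effect_sd SD of per-type log2 RNA shifts.
#' @param type_effect Optional fixed per-type log2 RNA shifts (length of
#'   `tumor_types`); drawn Normal(0, `type_effect_sd`) when `NULL`. Fix this
#'   (and the per-locus vectors) to hold the generative universe constant
#'   across replicates in parameter-recovery experiments.
#' @param efficiency Optional per-locus true efficiency (TRTs per TPM);
#'   drawn log-normal (meanlog `log(0.05)`, sdlog 1) when `NULL`.
#' @param run_on_fraction Per-locus fraction of transcripts reading through
#'   the internal polyadenylation site (scalar or length `n_loci`); only
#'   run-on transcripts can produce transduction-bearing RTs.
#' @param alpha_true Effect of p53 mutation on log2 locus RNA.
#' @param tau_prime_true Direct (RNA-independent) effect of p53 mutation on
#'   log RT exposure.
#' @param rt_background Poisson mean of non-locus-attributed RT events.
#' @param intronic_mean Mean RNA-seq intronic rate.
#' @param intronic_slope Contamination slope of log2 observed RNA on
#'   (intronic rate - mean).
#' @param coverage_slope Contamination slope of log2 observed total RT on
#'   (tumor coverage - 60).
#' @param lfs_prob Probability that a p53-mutant sample carries a germline
#'   (LFS) variant.
#' @param genes Tibble describing additional mutated genes: columns `gene`,
#'   `prob`, `rna_effect`, `rt_effect` (log2 units), `stratum` (`"all"`,
#'   `"p53_mut"`, `"p53_wt"`).
#' @param rt_death_threshold Survival threshold used by the `rt_selection`
#'   scenario: simulated p53-WT samples whose total RT exceeds it are
#'   removed and redrawn.
#' @param seed Integer seed.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_samples = 500,
                          tumor_types = c("ESCA", "LUSC", "COAD", "BRCA"),
                          type_props = c(0.25, 0.3, 0.2, 0.25),
                          p53_mut_prob = c(0.7, 0.7, 0.5, 0.35),
                          n_loci = 40,
                          baseline_log2 = NULL,
                          dispersion = 1,
                          type_effect_sd = 0.5,
                          type_effect = NULL,
                          efficiency = NULL,
                          run_on_fraction = 0.3,
                          alpha_true = 1.0,
                          tau_prime_true = 0.5,
                          rt_background = 5,
                          intronic_mean = 0.2,
                          intronic_slope = 2,
                          coverage_slope = 0.02,
                          lfs_prob = 0.02,
                          genes = NULL,
                          rt_death_threshold = 20,
                          seed = 1L) {
  if (abs(sum(type_props) - 1) > 1e-8) abort("type_props must sum to 1")
  if (any(type_props <= 0)) abort("degenerate type proportions", class = "l1rt_degenerate")
  if (length(p53_mut_prob) == 1) p53_mut_prob <- rep(p53_mut_prob, length(tumor_types))
  if (dispersion <= 0) abort("dispersion must be > 0")
  if (!is.null(efficiency) && any(efficiency < 0)) abort("efficiencies must be >= 0")
  if (is.null(genes)) {
    genes <- tibble(
      gene = sprintf("G%d", 1:6),
      prob = c(0.3, 0.25, 0.2, 0.15, 0.12, 0.1),
      rna_effect = 0, rt_effect = 0, stratum = "all"
    )
  }
  structure(as.list(environment()), class = "cohort_params")
}

# draw the per-sample annotation block (types, p53, lfs, genes, qc)
draw_samples <- function(p, n) {
  ttype <- sample(p$tumor_types, n, replace = TRUE, prob = p$type_props)
  pmut <- p$p53_mut_prob[match(ttype, p$tumor_types)]
  p53 <- rbinom(n, 1, pmut)
  lfs <- as.integer(p53 == 1 & runif(n) < p$lfs_prob)
  qc <- tibble(
    intronic_rate = stats::rbeta(n, 2, 8) * p$intronic_mean / 0.2,
    tumor_mean_read_length = 150 + rnorm(n, 0, 1),
    tumor_coverage = pmax(50, rnorm(n, 60, 8)),
    tumor_mean_base_quality = rnorm(n, 30, 0.8),
    tumor_chimeric_read_fraction = stats::rbeta(n, 2, 198),
    tumor_clipped_base_fraction = stats::rbeta(n, 3, 97),
    normal_mean_read_length = 150 + rnorm(n, 0, 1),
    normal_coverage = pmax(20, rnorm(n, 30, 5)),
    normal_mean_base_quality = rnorm(n, 30, 0.8),
    normal_chimeric_read_fraction = stats::rbeta(n, 2, 198),
    normal_clipped_base_fraction = stats::rbeta(n, 3, 97)
  )
  gmat <- matrix(
    vapply(seq_len(nrow(p$genes)), function(g) rbinom(n, 1, p$genes$prob[g]),
           integer(n)),
    nrow = n, dimnames = list(NULL, p$genes$gene)
  )
  list(ttype = ttype, p53 = p53, lfs = lfs, qc = qc, gmat = gmat)
}

# simulate locus RNA/TRT and totals for a fixed annotation block
draw_omics <- function(p, ann, truth) {
  n <- length(ann$ttype)
  L <- p$n_loci
  type_idx <- match(ann$ttype, p$tumor_types)
  mu <- outer(truth$baseline, rep(1, n)) +
    rep(1, L) %o% (p$alpha_true * ann$p53 + truth$type_effect[type_idx])
  if (any(p$genes$rna_effect != 0)) {
    for (g in seq_len(nrow(p$genes))) {
      gr <- p$genes[g, ]
      if (gr$rna_effect == 0) next
      in_stratum <- switch(gr$stratum, all = TRUE,
                           p53_mut = ann$p53 == 1, p53_wt = ann$p53 == 0)
      mu <- mu + rep(1, L) %o% (gr$rna_effect * ann$gmat[, gr$gene] * in_stratum)
    }
  }
  log2rna <- mu + matrix(rnorm(L * n, 0, p$dispersion), L, n)
  tpm_true <- 2^log2rna
  exposure <- exp(p$tau_prime_true * ann$p53)
  if (any(p$genes$rt_effect != 0)) {
    for (g in seq_len(nrow(p$genes))) {
      gr <- p$genes[g, ]
      if (gr$rt_effect == 0) next
      in_stratum <- switch(gr$stratum, all = TRUE,
                           p53_mut = ann$p53 == 1, p53_wt = ann$p53 == 0)
      exposure <- exposure * 2^(gr$rt_effect * ann$gmat[, gr$gene] * in_stratum)
    }
  }
  lambda <- (truth$efficiency * truth$run_on) * tpm_true *
    rep(1, L) %o% exposure
  trt <- matrix(rpois(L * n, lambda), L, n)
  total_rt <- colSums(trt) + rpois(n, p$rt_background)
  # technical contamination of the observed values
  tpm_obs <- tpm_true * rep(1, L) %o%
    2^(p$intronic_slope * (ann$qc$intronic_rate - p$intronic_mean))
  rt_obs <- round(total_rt * 2^(p$coverage_slope * (ann$qc$tumor_coverage - 60)))
  list(tpm = tpm_obs, trt = trt, total_rt = as.integer(rt_obs),
       total_rt_true = total_rt)
}

#' Simulate a synthetic multi-omic cohort
#'
#' @param params A [cohort_params()] object.
#' @return List of class `l1_cohort`:
#'   * `samples`: tibble with `sample_id`, `tumor_type`, `p53_mut`, `lfs`,
#'     gene mutation flags, `total_rt`, and the QC covariates,
#'   * `rna`: loci-by-samples TPM matrix (observed, QC-contaminated),
#'   * `trt`: loci-by-samples TRT count matrix,
#'   * `truth`: the planted parameters (baselines, type effects, per-locus
#'     efficiencies and run-on fractions, `alpha_true`, `tau_prime_true`).
#' @export
simulate_cohort <- function(params = cohort_params()) {
  p <- params
  withr::local_seed(p$seed)
  L <- p$n_loci
  truth <- list(
    baseline = p$baseline_log2 %||% runif(L, -3, 2),
    type_effect = setNames(
      p$type_effect %||% rnorm(length(p$tumor_types), 0, p$type_effect_sd),
      p$tumor_types),
    efficiency = p$efficiency %||% stats::rlnorm(L, log(0.05), 1),
    run_on = rep(p$run_on_fraction, length.out = L),
    alpha_true = p$alpha_true, tau_prime_true = p$tau_prime_true
  )
  ann <- draw_samples(p, p$n_samples)
  om <- draw_omics(p, ann, truth)
  assemble_cohort(p, ann, om, truth)
}

assemble_cohort <- function(p, ann, om, truth) {
  n <- length(ann$ttype)
  loci <- sprintf("L1_locus_%02d", seq_len(p$n_loci))
  rna <- om$tpm; trt <- om$trt
  dimnames(rna) <- dimnames(trt) <- list(loci, sprintf("s%04d", seq_len(n)))
  samples <- dplyr::bind_cols(
    tibble(sample_id = colnames(rna), tumor_type = ann$ttype,
           p53_mut = ann$p53, lfs = ann$lfs),
    as_tibble(ann$gmat),
    tibble(total_rt = om$total_rt),
    ann$qc
  )
  structure(list(samples = samples, rna = rna, trt = trt, truth = truth,
                 params = p), class = "l1_cohort")
}

#' Simulate a cohort under a named p53-regulation scenario
#'
#' Three generative scenarios for how p53 could shape the joint distribution
#' of L1 RNA and RT burden:
#' * `expression_only`: p53 regulates L1 transcription only
#'   (`tau_prime_true = 0`); any apparent direct RT effect downstream is a
#'   false positive.
#' * `rt_selection`: p53 does not regulate expression (`alpha_true = 0`),
#'   but wild-type p53 kills cells with high RT burden: simulated WT samples
#'   with total RT above `rt_death_threshold` are censored and redrawn to
#'   preserve the sample count.
#' * `dual`: both effects are planted.
#'
#' @param model `"expression_only"`, `"rt_selection"`, or `"dual"`.
#' @param params A [cohort_params()] object; its `alpha_true` /
#'   `tau_prime_true` are overridden per the scenario.
#' @return An `l1_cohort` (see [simulate_cohort()]).
#' @export
simulate_p53_scenario <- function(model = c("expression_only", "rt_selection", "dual"),
                                  params = cohort_params()) {
  model <- rlang::arg_match(model)
  p <- params
  # the scenarios are focused generative experiments: p53 status is drawn
  # independently of tumor type so no type-confounded association leaks into
  # the mediation fit
  p$p53_mut_prob <- rep(mean(p$p53_mut_prob), length(p$tumor_types))
  if (model == "expression_only") {
    p$tau_prime_true <- 0
  } else if (model == "rt_selection") {
    p$alpha_true <- 0
    p$tau_prime_true <- 0
  }
  co <- simulate_cohort(p)
  if (model == "rt_selection") {
    withr::local_seed(p$seed + 1L)
    truth <- co$truth
    for (iter in 1:100) {
      bad <- which(co$samples$p53_mut == 0 & co$samples$total_rt > p$rt_death_threshold)
      if (!length(bad)) break
      # cell death: redraw the censored WT samples (annotation and omics)
      repl <- draw_samples(p, length(bad))
      repl$p53 <- rep(0L, length(bad))
      repl$lfs <- rep(0L, length(bad))
      om2 <- draw_omics(p, repl, truth)
      co$samples$tumor_type[bad] <- repl$ttype
      co$samples[bad, names(repl$qc)] <- repl$qc
      co$samples[bad, colnames(repl$gmat)] <-
        as_tibble(matrix(repl$gmat, ncol = ncol(repl$gmat),
                         dimnames = list(NULL, colnames(repl$gmat))))
      co$samples$total_rt[bad] <- om2$total_rt
      co$rna[, bad] <- om2$tpm
      co$trt[, bad] <- om2$trt
    }
  }
  co$scenario <- model
  co
}

#' QC-adjust a synthetic cohort
#'
#' Applies [adjust_rna()] and [adjust_rt()] to the cohort's observed values:
#' total and per-locus RNA against intronic rate, total and per-locus RT
#' against the ten WGS metrics.
#'
#' @param cohort An `l1_cohort`.
#' @return The cohort with an `adj` element: `rna` / `trt` (adjusted log2
#'   matrices), `total_rna`, `total_rt` (adjusted log2 vectors).
#' @export
cohort_adjust <- function(cohort) {
  s <- cohort$samples
  wgs_cols <- c("tumor_mean_read_length", "tumor_coverage", "tumor_mean_base_quality",
                "tumor_chimeric_read_fraction", "tumor_clipped_base_fraction",
                "normal_mean_read_length", "normal_coverage", "normal_mean_base_quality",
                "normal_chimeric_read_fraction", "normal_clipped_base_fraction")
  covs <- as.matrix(s[wgs_cols])
  cohort$adj <- list(
    rna = adjust_rna(cohort$rna, s$intronic_rate),
    trt = adjust_rt(cohort$trt, covs),
    total_rna = adjust_rna(colSums(cohort$rna), s$intronic_rate),
    total_rt = adjust_rt(s$total_rt, covs)
  )
  cohort
}

#' Write a cohort as TSV files
#'
#' One wide sample table plus two locus matrices.
#'
#' @param cohort An `l1_cohort`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_cohort_tsv <- function(cohort, prefix) {
  paths <- paste0(prefix, c("_samples.tsv", "_rna.tsv", "_trt.tsv"))
  readr::write_tsv(cohort$samples, paths[1])
  readr::write_tsv(as_tibble(cohort$rna, rownames = "locus"), paths[2])
  readr::write_tsv(as_tibble(cohort$trt, rownames = "locus"), paths[3])
  invisible(paths)
}
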