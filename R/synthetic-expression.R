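#' Configuration for the synthetic study generator
#'
#' Defines a five-condition two-genotype design mirroring the study
#' layout (wild type untreated / +Cu / +Cu-ionophore; mutant untreated /
#' +Cu-ionophore) with planted regulon classes:
#'
#' * `aft` — iron-uptake regulon, induced by the copper ionophore only;
#' * `cth2` — iron-sparing targets, repressed by the ionophore only;
#' * `ace1` — copper-detoxification regulon, induced equally by copper
#'   with or without ionophore;
#' * `mac1` — copper-uptake regulon, repressed equally by both;
#' * `yap5` — iron-surplus regulon, modestly repressed by the ionophore;
#' * `cand_aft`, `cand_cth2` — genes that behave like `aft`/`cth2` but
#'   whose regulation is withheld from the emitted annotation
#'   ("unknown"), carrying planted promoter/3'-UTR motifs so candidate
#'   nomination can be validated against ground truth;
#' * `null` — unresponsive background genes.
#'
#' Effect ranges default to the printed extremes of the study's threshold
#' tables (iron regulon up 4–27x, copper regulon up 4–19x, iron-sparing
#' down 2–5x, copper-uptake down 5–22x, iron-surplus down 1.2–2x).
#' Candidate-class effects are drawn from the upper parts of those ranges
#' (down 3–5x, up 10–27x) so planted candidates clear the 2-fold
#' significance rule at the default noise level.
#'
#' @param n_genes named integer vector of genes per class.
#' @param effect_ranges named list of `c(lo, hi)` multiplicative fold
#'   ranges (fold-increase for up classes, fold-decrease for down
#'   classes).
#' @param cu_only_sd SD of the near-unity copper-only effect drawn for
#'   iron-responsive classes (their response is ionophore-specific).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   replicate noise (>= 0).
#' @param fra2_fraction_range range in [0,1] from which each
#'   iron-responsive gene's Fra2-dependent fraction is drawn.
#' @param n_replicates replicates per condition (default 3).
#' @param baseline_range untreated abundance range (RPKM), sampled
#'   log-uniformly.
#' @param promoter_len,utr3_len region lengths in nucleotides.
#' @param embed_rate fraction of eligible genes receiving an embedded
#'   consensus motif instance.
#' @param seed integer RNG seed; all generators are deterministic given
#'   the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = c(aft = 20, cth2 = 12, ace1 = 6, mac1 = 8,
                                   yap5 = 3, cand_aft = 1, cand_cth2 = 9,
                                   null = 150),
                       effect_ranges = list(
                         aft = c(4, 27), cth2 = c(2, 5), ace1 = c(4, 19),
                         mac1 = c(5, 22), yap5 = c(1.2, 2),
                         cand_aft = c(10, 27), cand_cth2 = c(3, 5)
                       ),
                       cu_only_sd = 0.1,
                       noise_cv = 0.1,
                       fra2_fraction_range = c(0, 1),
                       n_replicates = 3,
                       baseline_range = c(5, 500),
                       promoter_len = 600, utr3_len = 200,
                       embed_rate = 1,
                       seed = 1) {
  known <- c("aft", "cth2", "ace1", "mac1", "yap5",
             "cand_aft", "cand_cth2", "null")
  n_genes <- n_genes[n_genes > 0]
  if (length(n_genes) == 0) stop("empty class set")
  if (!all(names(n_genes) %in% known)) {
    stop("unknown class in n_genes: ",
         paste(setdiff(names(n_genes), known), collapse = ", "))
  }
  if (any(n_genes != round(n_genes))) stop("gene counts must be integers")
  if (n_replicates < 1) stop("zero replicates")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  for (cls in setdiff(names(n_genes), "null")) {
    r <- effect_ranges[[cls]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
      stop("effect_ranges[['", cls, "']] must be c(lo, hi) with 0 < lo <= hi")
    }
  }
  if (fra2_fraction_range[1] < 0 || fra2_fraction_range[2] > 1 ||
      fra2_fraction_range[1] > fra2_fraction_range[2]) {
    stop("fra2_fraction_range must lie within [0, 1]")
  }
  if (promoter_len < 10 || utr3_len < 10) stop("region lengths too short")
  if (embed_rate < 0 || embed_rate > 1) stop("embed_rate must be in [0, 1]")
  structure(
    list(n_genes = n_genes, effect_ranges = effect_ranges,
         cu_only_sd = cu_only_sd, noise_cv = noise_cv,
         fra2_fraction_range = fra2_fraction_range,
         n_replicates = as.integer(n_replicates),
         baseline_range = baseline_range,
         promoter_len = as.integer(promoter_len),
         utr3_len = as.integer(utr3_len),
         embed_rate = embed_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Condition design: genotype x treatment groups present in the study.
sim_conditions <- function() {
  data.frame(
    genotype = c("wt", "wt", "wt", "fra2", "fra2"),
    condition = c("untreated", "cu", "cu_bpq", "untreated", "cu_bpq"),
    stringsAsFactors = FALSE
  )
}

# Per-gene true multiplicative effects for each condition.
sim_truth_effects <- function(config) {
  classes <- rep(names(config$n_genes), config$n_genes)
  n <- length(classes)
  gene <- sprintf("%s%03d", toupper(gsub("_", "", classes)),
                  unlist(lapply(config$n_genes, seq_len)))
  draw <- function(cls) runif(1, config$effect_ranges[[cls]][1],
                              config$effect_ranges[[cls]][2])
  near1 <- function() max(rnorm(1, 1, config$cu_only_sd), 0.5)
  e_bpq <- numeric(n); e_cu <- numeric(n); f <- numeric(n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    if (cls %in% c("aft", "cand_aft")) {
      e_bpq[i] <- draw(cls); e_cu[i] <- near1()
    } else if (cls %in% c("cth2", "cand_cth2", "yap5")) {
      e_bpq[i] <- 1 / draw(cls); e_cu[i] <- near1()
    } else if (cls == "ace1") {
      e_bpq[i] <- draw(cls); e_cu[i] <- e_bpq[i]
    } else if (cls == "mac1") {
      e_bpq[i] <- 1 / draw(cls); e_cu[i] <- e_bpq[i]
    } else { # null
      e_bpq[i] <- 1; e_cu[i] <- 1
    }
    f[i] <- if (cls %in% c("aft", "cand_aft", "cth2", "cand_cth2", "yap5")) {
      runif(1, config$fra2_fraction_range[1], config$fra2_fraction_range[2])
    } else 0
  }
  baseline <- exp(runif(n, log(config$baseline_range[1]),
                        log(config$baseline_range[2])))
  data.frame(gene = gene, class = classes, baseline = baseline,
             effect_cu_bpq = e_bpq, effect_cu = e_cu, fra2_fraction = f,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Expected abundance of gene *g* in a condition is its baseline times the
#' class effect for that condition. In the mutant (*fra2* deletion)
#' background, the untreated expectation of an iron-responsive gene is
#' `baseline * (1 + f_g * (effect - 1))` — the fraction `f_g` of the full
#' treated response already de-repressed by loss of the repressor — and
#' the treated expectation is the full `baseline * effect`. Replicate
#' noise is multiplicative log-normal with the configured CV and unit
#' mean, so `noise_cv = 0` reproduces the expectations exactly.
#'
#' @param config a [sim_config()].
#' @return `list(expression = expr_matrix (RPKM), truth = sim_truth data
#'   frame)`. The truth records class, baseline, per-condition effects
#'   and the Fra2 fraction of every gene.
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    truth <- sim_truth_effects(config)
    conds <- sim_conditions()
    n_rep <- config$n_replicates
    expected <- cbind(
      wt_untreated = truth$baseline,
      wt_cu = truth$baseline * truth$effect_cu,
      wt_cu_bpq = truth$baseline * truth$effect_cu_bpq,
      fra2_untreated = truth$baseline *
        (1 + truth$fra2_fraction * (truth$effect_cu_bpq - 1)),
      fra2_cu_bpq = truth$baseline * truth$effect_cu_bpq
    )
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    cols <- list(); sheet <- list()
    for (j in seq_len(nrow(conds))) {
      for (r in seq_len(n_rep)) {
        id <- sprintf("%s_%s_%d", conds$genotype[j], conds$condition[j], r)
        noise <- rlnorm(nrow(truth), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        cols[[id]] <- expected[, j] * noise
        sheet[[id]] <- data.frame(
          sample = id, genotype = conds$genotype[j],
          condition = conds$condition[j], replicate = r,
          stringsAsFactors = FALSE
        )
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- truth$gene
    samples <- do.call(rbind, sheet)
    rownames(samples) <- NULL
    class(truth) <- c("sim_truth", "data.frame")
    list(expression = expression_matrix(values, samples, unit = "rpkm"),
         truth = truth)
  })
}

#' Regulon annotation implied by a ground truth
#'
#' Candidate and null classes are reported as `"unknown"`, mimicking an
#' annotation compiled before the candidates were characterised; this is
#' the annotation a fingerprint analysis of the synthetic data should be
#' given.
#'
#' @param truth a `sim_truth` data frame from [gen_expression()].
#' @return Data frame `gene`, `class`.
#' @export
annotation_from_truth <- function(truth) {
  cls <- truth$class
  cls[cls %in% c("cand_aft", "cand_cth2", "null")] <- "unknown"
  data.frame(gene = truth$gene, class = cls, stringsAsFactors = FALSE)
}
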