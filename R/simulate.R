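#' Specification of a synthetic two-class survival cohort
#'
#' Describes the generative model used by [generate_expression()] and
#' [generate_survival()]: independent Gaussian baseline expression, planted
#' class-2 mean shifts on chosen genes, planted class-specific correlations
#' on chosen kinase-substrate pairs (bivariate Gaussian per pair), and
#' Weibull proportional-hazards event times driven by node and/or edge
#' features, with uniform censoring calibrated to a target censored
#' fraction.
#'
#' @param network A [ks_network()]; its node set defines the simulated
#'   genes.
#' @param n_class1,n_class2 Samples per class (each >= 3).
#' @param baseline_mean,baseline_sd Per-gene Gaussian baseline parameters.
#' @param node_effects Data frame (`gene`, `delta`): mean shift added to
#'   the gene in class 2.
#' @param edge_effects Data frame (`kinase`, `substrate`, `rho1`, `rho2`):
#'   target within-class Pearson correlations (each in (-1, 1)) for a
#'   network pair. Pairs are drawn sequentially from bivariate Gaussians;
#'   two edge effects may not share a gene (jointly modelling overlapping
#'   pairs is out of scope, and silent overwriting would corrupt the first
#'   pair's correlation).
#' @param survival_betas Data frame (`feature`, `beta`): log-hazard
#'   coefficients on node feature IDs (gene symbols) or edge feature IDs
#'   (`"KINASE-SUBSTRATE"`), applied to the pooled-z node values and the
#'   class-conditional edge values.
#' @param weibull_shape,weibull_scale Baseline event-time distribution.
#' @param censor_fraction Target censored proportion in \[0, 1).
#' @param stage_probs List of two probability vectors (class 1, class 2)
#'   over the levels of the categorical "stage" covariate.
#' @param seed Integer RNG seed; all draws are reachable from it.
#' @return Validated list of class `ks_cohort_spec`.
#' @export
cohort_spec <- function(network, n_class1, n_class2,
                        baseline_mean = 0, baseline_sd = 1,
                        node_effects = NULL, edge_effects = NULL,
                        survival_betas = NULL,
                        weibull_shape = 1.5, weibull_scale = 5,
                        censor_fraction = 0.2,
                        stage_probs = list(c(I = 0.5, II = 0.35, III = 0.15),
                                           c(I = 0.3, II = 0.4, III = 0.3)),
                        seed = 1L) {
  spec <- structure(list(
    network = network, n_class1 = as.integer(n_class1),
    n_class2 = as.integer(n_class2),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    node_effects = node_effects, edge_effects = edge_effects,
    survival_betas = survival_betas,
    weibull_shape = weibull_shape, weibull_scale = weibull_scale,
    censor_fraction = censor_fraction, stage_probs = stage_probs,
    seed = as.integer(seed)), class = "ks_cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "ks_cohort_spec"))
  if (!inherits(spec$network, "ks_network") || !nrow(spec$network))
    stop("`network` must be a non-empty ks_network")
  if (spec$n_class1 < 3 || spec$n_class2 < 3)
    stop("each class needs >= 3 samples")
  if (spec$baseline_sd <= 0) stop("`baseline_sd` must be positive")
  if (!(spec$censor_fraction >= 0 && spec$censor_fraction < 1))
    stop("`censor_fraction` must be in [0, 1)")
  if (spec$weibull_shape <= 0 || spec$weibull_scale <= 0)
    stop("Weibull parameters must be positive")
  genes <- network_genes(spec$network)
  ne <- spec$node_effects
  if (!is.null(ne)) {
    if (!all(c("gene", "delta") %in% names(ne)))
      stop("`node_effects` needs columns gene, delta")
    bad <- setdiff(ne$gene, genes)
    if (length(bad)) stop("node_effects gene(s) not in network: ",
                          paste(bad, collapse = ", "))
    if (anyDuplicated(ne$gene)) stop("duplicate node_effects genes")
  }
  ee <- spec$edge_effects
  if (!is.null(ee)) {
    if (!all(c("kinase", "substrate", "rho1", "rho2") %in% names(ee)))
      stop("`edge_effects` needs columns kinase, substrate, rho1, rho2")
    if (any(abs(c(ee$rho1, ee$rho2)) >= 1))
      stop("edge_effects correlations must lie in (-1, 1)")
    in_net <- paste(ee$kinase, ee$substrate) %in%
      paste(spec$network$kinase, spec$network$substrate)
    if (any(!in_net))
      stop("edge_effects pair(s) not in network: ",
           paste(paste0(ee$kinase[!in_net], "-", ee$substrate[!in_net]),
                 collapse = ", "))
    eff_genes <- c(ee$kinase, ee$substrate)
    if (anyDuplicated(eff_genes))
      stop("edge_effects share gene(s): ",
           paste(unique(eff_genes[duplicated(eff_genes)]), collapse = ", "),
           " (overlapping planted correlations are not supported)")
  }
  sb <- spec$survival_betas
  if (!is.null(sb)) {
    if (!all(c("feature", "beta") %in% names(sb)))
      stop("`survival_betas` needs columns feature, beta")
    known <- c(genes, edge_ids(spec$network))
    bad <- setdiff(sb$feature, known)
    if (length(bad))
      stop("survival_betas feature(s) unknown: ",
           paste(bad, collapse = ", "))
  }
  sp <- spec$stage_probs
  if (!is.list(sp) || length(sp) != 2 ||
      length(sp[[1]]) != length(sp[[2]]) ||
      any(abs(vapply(sp, sum, 0) - 1) > 1e-8))
    stop("`stage_probs` must be two probability vectors of equal length")
  invisible(spec)
}

#' Generate synthetic expression for a cohort specification
#'
#' Genes are the nodes of `spec$network`. Every gene starts as independent
#' Gaussian(baseline_mean, baseline_sd) in both classes; each planted edge
#' effect replaces its pair's rows with a bivariate Gaussian draw at the
#' class-specific target correlation (same marginal mean/sd); node effects
#' then shift the class-2 mean of their gene by delta. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A [ks_expr()] with classes `"C1"`/`"C2"`, samples
#'   `S0001, S0002, ...` (class 1 first).
#' @export
generate_expression <- function(spec) {
  validate_cohort_spec(spec)
  genes <- network_genes(spec$network)
  n1 <- spec$n_class1; n2 <- spec$n_class2; n <- n1 + n2
  samples <- sprintf("S%04d", seq_len(n))
  cls <- rep(c("C1", "C2"), c(n1, n2))
  vals <- withr::with_seed(spec$seed, {
    m <- matrix(stats::rnorm(length(genes) * n, spec$baseline_mean,
                             spec$baseline_sd),
                nrow = length(genes), dimnames = list(genes, samples))
    ee <- spec$edge_effects
    if (!is.null(ee)) for (i in seq_len(nrow(ee))) {
      for (k in 1:2) {
        idx <- if (k == 1) seq_len(n1) else n1 + seq_len(n2)
        rho <- if (k == 1) ee$rho1[i] else ee$rho2[i]
        z1 <- stats::rnorm(length(idx))
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(length(idx))
        m[ee$kinase[i], idx] <- spec$baseline_mean + spec$baseline_sd * z1
        m[ee$substrate[i], idx] <- spec$baseline_mean + spec$baseline_sd * z2
      }
    }
    ne <- spec$node_effects
    if (!is.null(ne)) for (i in seq_len(nrow(ne)))
      m[ne$gene[i], cls == "C2"] <- m[ne$gene[i], cls == "C2"] + ne$delta[i]
    m
  })
  ks_expr(vals, cls)
}

#' Generate survival outcomes under a Weibull proportional-hazards model
#'
#' Event times follow a Weibull baseline with multiplicative hazards:
#' `T = scale * (-log(U) / exp(lp))^(1/shape)` with linear predictor
#' `lp = sum(beta_f * feature_f)`, where node features are pooled gene-level
#' z-scores of `expr` and edge features come from [edge_transform()] (the
#' same transform the analysis pipeline uses). When `censor_fraction > 0`,
#' an independent Uniform(0, c) censoring time is drawn with c calibrated
#' by bisection so the realized censored proportion hits the target within
#' 0.02 (capped by the achievable range). A categorical "stage" covariate
#' with class-dependent frequencies is added to exercise multivariate
#' models. Deterministic given `spec$seed` (offset stream, so expression
#' and outcomes are independent).
#'
#' @param expr A [ks_expr()], typically from [generate_expression()].
#' @param network The [ks_network()] defining edge features.
#' @param spec The [cohort_spec()] carrying hazards, Weibull and censoring
#'   parameters.
#' @return Clinical data frame: sample_id, class, time, event, stage.
#' @export
generate_survival <- function(expr, network, spec) {
  validate_cohort_spec(spec)
  n <- ncol(expr$values)
  lp <- rep(0, n)
  sb <- spec$survival_betas
  if (!is.null(sb) && nrow(sb)) {
    feats <- suppressMessages(
      edge_transform(log2_zscore(expr, log2 = FALSE), network))
    bad <- setdiff(sb$feature, rownames(feats$values))
    if (length(bad))
      stop("survival feature(s) not constructible: ",
           paste(bad, collapse = ", "))
    lp <- as.vector(t(feats$values[sb$feature, , drop = FALSE]) %*% sb$beta)
  }
  withr::with_seed(spec$seed + 1L, {
    u <- stats::runif(n)
    t_event <- spec$weibull_scale *
      (-log(u) / exp(lp))^(1 / spec$weibull_shape)
    if (spec$censor_fraction > 0) {
      v <- stats::runif(n)
      cens_frac <- function(c_max) mean(t_event > c_max * v)
      lo <- 1e-9; hi <- max(t_event) * 2
      while (cens_frac(hi) > spec$censor_fraction && hi < 1e12) hi <- hi * 4
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (cens_frac(mid) > spec$censor_fraction) lo <- mid else hi <- mid
      }
      c_time <- ((lo + hi) / 2) * v
      time <- pmin(t_event, c_time)
      event <- as.integer(t_event <= c_time)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    time <- pmax(time, .Machine$double.eps)
    lv <- names(spec$stage_probs[[1]])
    if (is.null(lv)) lv <- paste0("stage", seq_along(spec$stage_probs[[1]]))
    stage <- character(n)
    k1 <- expr$class == levels(expr$class)[1]
    stage[k1] <- sample(lv, sum(k1), replace = TRUE,
                        prob = spec$stage_probs[[1]])
    stage[!k1] <- sample(lv, sum(!k1), replace = TRUE,
                         prob = spec$stage_probs[[2]])
    data.frame(sample_id = colnames(expr$values),
               class = as.character(expr$class),
               time = time, event = event, stage = stage,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full two-class survival cohort
#'
#' Convenience wrapper: [generate_expression()] then [generate_survival()],
#' bundled with the planted truth.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `ks_cohort`: list with `expression`
#'   ([ks_expr()]), `clinical` (data frame), `network`, and `truth` (the
#'   planted node_effects, edge_effects, survival_betas).
#' @export
simulate_cohort <- function(spec) {
  expr <- generate_expression(spec)
  clinical <- generate_survival(expr, spec$network, spec)
  structure(list(expression = expr, clinical = clinical,
                 network = spec$network,
                 truth = list(node_effects = spec$node_effects,
                              edge_effects = spec$edge_effects,
                              survival_betas = spec$survival_betas,
                              seed = spec$seed)),
            class = "ks_cohort")
}

#' @export
print.ks_cohort <- function(x, ...) {
  cat(sprintf("ks_cohort: %d genes x %d samples, %d network pair(s), %d event(s)\n",
              nrow(x$expression$values), ncol(x$expression$values),
              nrow(x$network), sum(x$clinical$event)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `expression.tsv`, `clinical.tsv`, `network.tsv` (all round-tripping
#' through the package readers losslessly) and `truth.yaml` listing the
#' planted effects in specification order.
#'
#' @param cohort A `ks_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent; must be non-empty).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ks_cohort"))
  if (!is.character(dir) || length(dir) != 1 || !nzchar(dir))
    stop("invalid output directory path: ",
         deparse(substitute(dir)), " = \"", dir, "\"")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             network = file.path(dir, "network.tsv"),
             truth = file.path(dir, "truth.yaml"))
  write_expression(cohort$expression$values, paths["expression"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_network(cohort$network, paths["network"])
  truth <- lapply(cohort$truth, function(x)
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i)
      as.list(x[i, , drop = FALSE])) else x)
  yaml::write_yaml(truth, paths["truth"])
  invisible(paths)
}

#' A ready-made cohort specification for demonstrations and tests
#'
#' Builds a disjoint kinase-substrate network (`KIN001-SUB001`, ...) of
#' `n_pairs` pairs and plants differential correlations (`rho` in class 1,
#' `-rho` in class 2) on the first `n_effect_pairs` pairs, a `delta` mean
#' shift on the first kinase without an edge effect, and log-hazard `beta`
#' on the first `n_hazard_edges` planted edges.
#'
#' @param seed RNG seed.
#' @param n_per_class Samples per class.
#' @param n_pairs Network size (disjoint pairs; 2 * n_pairs genes).
#' @param n_effect_pairs Pairs with planted differential correlation.
#' @param rho Planted correlation magnitude.
#' @param delta Planted class-2 mean shift on one non-effect kinase (0
#'   disables).
#' @param beta Log-hazard coefficient on the prognostic edges.
#' @param n_hazard_edges Number of planted edges driving the hazard.
#' @param censor_fraction Target censored proportion.
#' @param informative_stage Use class-dependent stage frequencies (TRUE) or
#'   identical ones (FALSE).
#' @return A [cohort_spec()].
#' @export
demo_cohort_spec <- function(seed = 1L, n_per_class = 150, n_pairs = 20,
                             n_effect_pairs = 2, rho = 0.6, delta = 1,
                             beta = 1, n_hazard_edges = min(2, n_effect_pairs),
                             censor_fraction = 0.2,
                             informative_stage = FALSE) {
  stopifnot(n_pairs >= n_effect_pairs, n_effect_pairs >= n_hazard_edges)
  net <- ks_network(sprintf("KIN%03d", seq_len(n_pairs)),
                    sprintf("SUB%03d", seq_len(n_pairs)))
  ee <- if (n_effect_pairs > 0)
    data.frame(kinase = net$kinase[seq_len(n_effect_pairs)],
               substrate = net$substrate[seq_len(n_effect_pairs)],
               rho1 = rho, rho2 = -rho)
  ne <- if (delta != 0 && n_pairs > n_effect_pairs)
    data.frame(gene = net$kinase[n_effect_pairs + 1], delta = delta)
  sb <- if (n_hazard_edges > 0)
    data.frame(feature = edge_ids(net)[seq_len(n_hazard_edges)],
               beta = beta)
  probs <- if (informative_stage)
    list(c(I = 0.5, II = 0.35, III = 0.15), c(I = 0.3, II = 0.4, III = 0.3))
  else list(c(I = 0.4, II = 0.4, III = 0.2), c(I = 0.4, II = 0.4, III = 0.2))
  cohort_spec(net, n_per_class, n_per_class,
              node_effects = ne, edge_effects = ee, survival_betas = sb,
              censor_fraction = censor_fraction, stage_probs = probs,
              seed = seed)
}
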