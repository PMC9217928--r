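# Seeded synthetic cohort generator. The defaults encode the study design
# this package analyses: AI (control) singleton pregnancies vs IVP transfers
# of two embryos per heifer, a two-component lognormal weight mixture whose
# upper component models overgrowth (LOS), sex-biased fetal loss between D56
# and D105 in the IVP arm, allometric D55 biometry, dam-correlated leukocyte
# count matrices, and qPCR CT tables.

# Typical D55 measurement magnitudes (cm) used as the allometric base shape;
# their product anchors the product-index scale.
.d55_base_shape <- c(AD = 1.75, AH = 1.72, TD = 1.90, TH = 1.70,
                     CRL = 4.55, HL = 2.00, BPD = 1.30)

# Sex x day lognormal weight parameters moment-matched to the observed
# control means/SDs (g): D56 M 8.78 +/- 1.33, F 8.50 +/- 1.59;
# D105 M 494.29 +/- 44.05, F 416.50 +/- 36.01.
default_weight_params <- function() {
  grid <- list(
    list(sex = "M", day = 56L,  mean = 8.78,   sd = 1.33),
    list(sex = "F", day = 56L,  mean = 8.50,   sd = 1.59),
    list(sex = "M", day = 105L, mean = 494.29, sd = 44.05),
    list(sex = "F", day = 105L, mean = 416.50, sd = 36.01)
  )
  do.call(rbind, lapply(grid, function(g) {
    p <- lnorm_params(g$mean, g$sd)
    data.frame(sex = g$sex, day = g$day, meanlog = p[["meanlog"]],
               sdlog = p[["sdlog"]], stringsAsFactors = FALSE)
  }))
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of the generator. Defaults emulate the
#' study conditions: 12 AI singleton pregnancies and 48 IVP recipients each
#' transferred two embryos (per-embryo implantation 0.56, matching the twin
#' fraction observed among IVP pregnancies), equal primary sex ratio,
#' IVP-specific excess loss of female fetuses by D105, a 30% overgrowth
#' mixture weight, lognormal weights moment-matched to the control
#' means/SDs, cube-root allometry of linear biometry with 5% measurement
#' noise, and negative-binomial leukocyte counts with dam-specific expression
#' profiles.
#'
#' @param seed Global integer seed; named substreams are derived from it per
#'   output table so enlarging one table never perturbs another.
#' @param n_ai_dams,n_ivp_dams Pregnant dams per arm.
#' @param embryos_per_ivp_transfer Embryos transferred per IVP recipient.
#' @param implantation_prob Per-embryo implantation probability in IVP dams.
#' @param p_female Primary probability a fetus is female.
#' @param female_loss_d105 IVP-specific excess probability a female fetus is
#'   lost between D56 and D105 (drives the D105 sex-ratio skew).
#' @param pi_los Probability an IVP fetus is drawn from the overgrowth
#'   component.
#' @param weight_params Data frame `sex`, `day`, `meanlog`, `sdlog` of the
#'   per-sex, per-day lognormal weight distributions (grams).
#' @param los_multiplier_meanlog,los_multiplier_sdlog Lognormal parameters of
#'   the overgrowth weight multiplier (mean > 1).
#' @param allometric_exponent Exponent linking linear biometry to weight
#'   (default 1/3: lengths scale with the cube root of mass).
#' @param measurement_cv Multiplicative noise CV on each biometric.
#' @param growth_divergence_d55 Attenuation of the overgrowth multiplier at
#'   the D55 ultrasound relative to D105 (0 = no divergence yet, 1 = full);
#'   models the partially established growth divergence at D55.
#' @param n_genes,n_de_genes Gene panel size and number of planted
#'   differentially expressed genes (extreme-dam signature).
#' @param n_stable_genes Number of housekeeping-like genes: highly
#'   expressed, no dam effect, near-Poisson dispersion (the population the
#'   reference-gene screen is meant to find).
#' @param de_log2fc Log2 fold change applied to planted genes in samples of
#'   dams flagged `extreme`.
#' @param dispersion_shape,dispersion_scale Gamma parameters of the gene-wise
#'   negative-binomial dispersions.
#' @param dam_effect_sd SD of the per-gene, per-dam log-scale random effect
#'   shared by a dam's D55 and D105 samples (the "clustered by animal"
#'   signal).
#' @param libsize_range Min/max expected library size (reads).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ai_dams = 12L,
                       n_ivp_dams = 48L,
                       embryos_per_ivp_transfer = 2L,
                       implantation_prob = 0.56,
                       p_female = 0.5,
                       female_loss_d105 = 0.6,
                       pi_los = 0.3,
                       weight_params = default_weight_params(),
                       los_multiplier_meanlog = log(1.4),
                       los_multiplier_sdlog = 0.25,
                       allometric_exponent = 1 / 3,
                       measurement_cv = 0.05,
                       growth_divergence_d55 = 0.25,
                       n_genes = 2000L,
                       n_de_genes = 50L,
                       n_stable_genes = 20L,
                       de_log2fc = 2,
                       dispersion_shape = 2,
                       dispersion_scale = 0.05,
                       dam_effect_sd = 0.25,
                       libsize_range = c(5e5, 1.5e6)) {
  cfg <- list(seed = check_count(seed, "seed"),
              n_ai_dams = check_count(n_ai_dams, "n_ai_dams"),
              n_ivp_dams = check_count(n_ivp_dams, "n_ivp_dams"),
              embryos_per_ivp_transfer = check_count(embryos_per_ivp_transfer, "embryos_per_ivp_transfer", 1L),
              implantation_prob = check_prob(implantation_prob, "implantation_prob"),
              p_female = check_prob(p_female, "p_female"),
              female_loss_d105 = check_prob(female_loss_d105, "female_loss_d105"),
              pi_los = check_prob(pi_los, "pi_los"),
              weight_params = weight_params,
              los_multiplier_meanlog = los_multiplier_meanlog,
              los_multiplier_sdlog = check_pos(los_multiplier_sdlog, "los_multiplier_sdlog", strict = FALSE),
              allometric_exponent = allometric_exponent,
              measurement_cv = check_pos(measurement_cv, "measurement_cv", strict = FALSE),
              growth_divergence_d55 = growth_divergence_d55,
              n_genes = check_count(n_genes, "n_genes", 1L),
              n_de_genes = check_count(n_de_genes, "n_de_genes"),
              n_stable_genes = check_count(n_stable_genes, "n_stable_genes"),
              de_log2fc = de_log2fc,
              dispersion_shape = check_pos(dispersion_shape, "dispersion_shape"),
              dispersion_scale = check_pos(dispersion_scale, "dispersion_scale"),
              dam_effect_sd = check_pos(dam_effect_sd, "dam_effect_sd", strict = FALSE),
              libsize_range = libsize_range)
  if (!is.data.frame(weight_params) ||
      !all(c("sex", "day", "meanlog", "sdlog") %in% names(weight_params)))
    bad_field("weight_params", "needs columns sex, day, meanlog, sdlog")
  if (any(weight_params$sdlog < 0)) bad_field("weight_params", "sdlog must be >= 0")
  if (!is.finite(de_log2fc)) bad_field("de_log2fc", "must be finite")
  if (!is.finite(los_multiplier_meanlog)) bad_field("los_multiplier_meanlog", "must be finite")
  if (!is.numeric(libsize_range) || length(libsize_range) != 2L ||
      libsize_range[1] <= 0 || diff(libsize_range) < 0)
    bad_field("libsize_range", "must be (min, max) with min > 0")
  if (cfg$n_de_genes > cfg$n_genes) bad_field("n_de_genes", "cannot exceed n_genes")
  if (cfg$n_de_genes + cfg$n_stable_genes > cfg$n_genes)
    bad_field("n_stable_genes", "n_de_genes + n_stable_genes cannot exceed n_genes")
  if (growth_divergence_d55 < 0 || growth_divergence_d55 > 1)
    bad_field("growth_divergence_d55", "must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

.weight_par <- function(cfg, sex, day) {
  wp <- cfg$weight_params
  # D55/D56 biometry shares the D56 weight distribution
  day <- if (day <= 56) 56L else 105L
  row <- wp[wp$sex == sex & wp$day == day, ]
  if (nrow(row) != 1L) bad_field("weight_params", sprintf("no entry for sex %s day %d", sex, day))
  row
}

#' Simulate a fetal cohort with D55 ultrasound biometry
#'
#' Draws dams, implantation, fetal sex (with IVP-specific female loss when
#' `day = 105`), collection weights from the sex/day lognormal times an
#' overgrowth multiplier for fetuses in the LOS component, and D55 ultrasound
#' measurements linked to weight by `m = base * (w / ref_w)^a * (1 + eps)`
#' with `eps ~ N(0, measurement_cv)`. At D55 the overgrowth multiplier is
#' attenuated by `growth_divergence_d55` (the growth divergence of LOS
#' fetuses is only partially established then).
#'
#' @param config A [sim_config()].
#' @param day Collection day, 56 or 105.
#' @return List with `fetuses` (data frame: `fetus_id`, `dam_id`, `group`,
#'   `sex`, `day`, `weight_g`, `twin`), `exams` (data frame of D55
#'   measurements, cm), and `truth` (per-fetus component labels and
#'   multipliers).
#' @export
simulate_cohort <- function(config, day = 105) {
  stopifnot(inherits(config, "sim_config"))
  if (!day %in% c(56, 105)) bad_field("day", "must be 56 or 105")
  with_seed(substream_seed(config$seed, paste0("cohort", day)), {
    rows <- list()
    for (i in seq_len(config$n_ai_dams)) {
      rows[[length(rows) + 1L]] <- list(dam = sprintf("AI%03d", i), group = "AI", n = 1L)
    }
    for (i in seq_len(config$n_ivp_dams)) {
      n_impl <- stats::rbinom(1L, config$embryos_per_ivp_transfer, config$implantation_prob)
      rows[[length(rows) + 1L]] <- list(dam = sprintf("IVP%03d", i), group = "IVP", n = n_impl)
    }
    fet <- list()
    for (r in rows) {
      if (r$n == 0L) next
      for (k in seq_len(r$n)) {
        sex <- if (stats::runif(1) < config$p_female) "F" else "M"
        # IVP females are preferentially lost between D56 and D105
        if (day == 105 && r$group == "IVP" && sex == "F" &&
            stats::runif(1) < config$female_loss_d105) next
        overgrown <- r$group == "IVP" && stats::runif(1) < config$pi_los
        mult <- if (overgrown)
          stats::rlnorm(1, config$los_multiplier_meanlog, config$los_multiplier_sdlog) else 1
        z <- stats::rnorm(1)
        fet[[length(fet) + 1L]] <- data.frame(
          dam_id = r$dam, group = r$group, sex = sex, day = day,
          z = z, mult = mult, overgrown = overgrown,
          twin = r$n > 1L, stringsAsFactors = FALSE)
      }
    }
    if (!length(fet)) stop("simulated cohort is empty; increase dam counts", call. = FALSE)
    fet <- do.call(rbind, fet)
    fet$fetus_id <- sprintf("%s_%s", fet$dam_id, ave(fet$dam_id, fet$dam_id, FUN = seq_along))
    wp <- do.call(rbind, lapply(seq_len(nrow(fet)), function(i) .weight_par(config, fet$sex[i], day)))
    fet$weight_g <- exp(wp$meanlog + wp$sdlog * fet$z) * fet$mult

    # D55 biometry: shared z, D56 weight scale, attenuated multiplier
    wp55 <- do.call(rbind, lapply(seq_len(nrow(fet)), function(i) .weight_par(config, fet$sex[i], 56)))
    mult55 <- exp(config$growth_divergence_d55 * log(fet$mult))
    w55 <- exp(wp55$meanlog + wp55$sdlog * fet$z) * mult55
    ref_w <- exp(mean(wp55$meanlog))
    nms <- names(.d55_base_shape)
    eps <- matrix(stats::rnorm(nrow(fet) * length(nms), 0, config$measurement_cv),
                  nrow = nrow(fet))
    meas <- outer(
      (w55 / ref_w)^config$allometric_exponent,
      .d55_base_shape) * (1 + eps)
    colnames(meas) <- nms
    exams <- data.frame(fetus_id = fet$fetus_id, day = 55L, meas,
                        stringsAsFactors = FALSE)
    truth <- list(component = stats::setNames(ifelse(fet$overgrown, "overgrown", "normal"),
                                              fet$fetus_id),
                  multiplier = stats::setNames(fet$mult, fet$fetus_id),
                  weight_d55 = stats::setNames(w55, fet$fetus_id),
                  ref_weight = ref_w)
    fetuses <- fet[, c("fetus_id", "dam_id", "group", "sex", "day", "weight_g", "twin")]
    rownames(fetuses) <- NULL
    list(fetuses = fetuses, exams = exams, truth = truth)
  })
}

#' Sample metadata for maternal leukocyte transcriptomes
#'
#' Builds one blood sample per dam per gestation day (55 and 105) for the
#' dams of a D105 cohort, mirroring the paired-sample design. Dams carrying
#' the two heaviest overgrown fetuses are flagged `extreme`.
#'
#' @param fetuses Fetus table from [simulate_cohort()] (day 105).
#' @param n_dams Number of dams to retain (heaviest-fetus-first among IVP,
#'   all AI; default all).
#' @return Data frame `sample_id`, `dam_id`, `day`, `group`, `n_fetuses`,
#'   `total_fetal_mass`, `extreme`.
#' @export
sample_meta_from_cohort <- function(fetuses, n_dams = NULL) {
  agg <- do.call(rbind, lapply(split(fetuses, fetuses$dam_id), function(d) {
    data.frame(dam_id = d$dam_id[1], group = d$group[1],
               n_fetuses = nrow(d), total_fetal_mass = sum(d$weight_g),
               max_weight = max(d$weight_g), stringsAsFactors = FALSE)
  }))
  labs <- classify_los(fetuses)
  dam_los <- vapply(agg$dam_id, function(d) {
    any(labs$labels$label[fetuses$dam_id == d] == "IVP-LOS")
  }, logical(1))
  agg$group <- ifelse(agg$group == "AI", "Control-AI",
                      ifelse(dam_los, "IVP-LOS", "IVP-Normal"))
  if (!is.null(n_dams) && n_dams < nrow(agg)) {
    keep_ai <- agg$dam_id[agg$group == "Control-AI"]
    keep_ivp <- agg$dam_id[order(-agg$max_weight)]
    keep_ivp <- setdiff(keep_ivp, keep_ai)[seq_len(max(0L, n_dams - length(keep_ai)))]
    agg <- agg[agg$dam_id %in% c(keep_ai, keep_ivp), ]
  }
  los_w <- agg$max_weight
  los_w[agg$group != "IVP-LOS"] <- -Inf
  extreme_dams <- agg$dam_id[order(-los_w)][seq_len(min(2L, sum(is.finite(los_w) & los_w > 0)))]
  meta <- do.call(rbind, lapply(c(55L, 105L), function(dy) {
    data.frame(sample_id = sprintf("D%d_%s", dy, agg$dam_id),
               dam_id = agg$dam_id, day = dy, group = agg$group,
               n_fetuses = agg$n_fetuses, total_fetal_mass = agg$total_fetal_mass,
               extreme = agg$dam_id %in% extreme_dams & agg$group == "IVP-LOS",
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  meta
}

#' Simulate a leukocyte RNA-seq count matrix
#'
#' Counts are drawn as
#' `NB(mean = L_j * q_g * 2^(dam profile + planted effect), dispersion phi_g)`
#' with gene-wise Gamma dispersions, a per-gene, per-dam lognormal expression
#' profile shared by a dam's two samples (producing the "clustered by
#' animal" structure), and `de_log2fc` applied to `n_de_genes` planted genes
#' in samples of dams flagged `extreme`.
#'
#' @param config A [sim_config()].
#' @param samples Sample metadata as from [sample_meta_from_cohort()].
#' @return List with `counts` (integer matrix genes x samples), `truth`
#'   (per-gene DE flag and log2 fold change, per-dam profile matrix, true
#'   library sizes, dispersions).
#' @export
simulate_counts <- function(config, samples) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(nrow(samples)) || nrow(samples) == 0L) bad_field("samples", "must be non-empty")
  req <- c("sample_id", "dam_id", "day", "group", "extreme")
  miss <- setdiff(req, names(samples))
  if (length(miss)) bad_field("samples", paste("missing columns:", paste(miss, collapse = ", ")))
  if (config$n_de_genes > config$n_genes) bad_field("n_de_genes", "cannot exceed n_genes")
  with_seed(substream_seed(config$seed, "counts"), {
    G <- config$n_genes
    S <- nrow(samples)
    genes <- sprintf("G%05d", seq_len(G))
    rel_expr <- stats::rlnorm(G, meanlog = 0, sdlog = 1.5)
    phi <- stats::rgamma(G, shape = config$dispersion_shape, scale = config$dispersion_scale)
    libsize <- stats::runif(S, config$libsize_range[1], config$libsize_range[2])
    dams <- unique(samples$dam_id)
    dam_prof <- matrix(stats::rnorm(G * length(dams), 0, config$dam_effect_sd),
                       nrow = G, dimnames = list(genes, dams))
    # housekeeping-like genes: high expression, no dam profile, near-Poisson
    stable_idx <- if (config$n_stable_genes > 0)
      seq.int(G - config$n_stable_genes + 1L, G) else integer(0)
    if (length(stable_idx)) {
      rel_expr[stable_idx] <- stats::rlnorm(length(stable_idx), meanlog = 2.5, sdlog = 0.3)
      phi[stable_idx] <- 1e-4
      dam_prof[stable_idx, ] <- 0
    }
    q <- rel_expr / sum(rel_expr)
    de_idx <- if (config$n_de_genes > 0) seq_len(config$n_de_genes) else integer(0)
    lfc <- numeric(G)
    lfc[de_idx] <- config$de_log2fc
    mu <- matrix(0, G, S, dimnames = list(genes, samples$sample_id))
    for (j in seq_len(S)) {
      eff <- dam_prof[, samples$dam_id[j]]
      if (isTRUE(samples$extreme[j])) eff <- eff + lfc * log(2)
      mu[, j] <- libsize[j] * q * exp(eff)
    }
    counts <- matrix(stats::rnbinom(G * S, size = rep(1 / pmax(phi, 1e-12), S), mu = as.vector(mu)),
                     G, S, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    truth <- list(de = stats::setNames(seq_len(G) %in% de_idx, genes),
                  stable = stats::setNames(seq_len(G) %in% stable_idx, genes),
                  log2fc = stats::setNames(lfc, genes),
                  dispersion = stats::setNames(phi, genes),
                  dam_profile = dam_prof,
                  libsize = stats::setNames(libsize, samples$sample_id))
    list(counts = counts, truth = truth)
  })
}

#' Simulate a qPCR CT table
#'
#' Reference genes have constant CT up to noise; the target's CT is shifted
#' down by `log2(fold)` in each sample, so the comparative-CT method should
#' recover the planted folds.
#'
#' @param config A [sim_config()] (used for the seed substream).
#' @param folds Named positive numeric: planted fold change per sample.
#' @param target Target gene name.
#' @param reference_genes Character vector of reference gene names.
#' @param ct_target_level,ct_ref_level Baseline CT levels (cycles).
#' @param noise_sd SD of Gaussian CT noise (cycles); 0 gives exact recovery.
#' @return Data frame `sample_id`, `gene`, `ct`, `role`.
#' @export
simulate_qpcr <- function(config, folds, target = "TTF1",
                          reference_genes = c("ECD", "NFKBIB", "VPS35L"),
                          ct_target_level = 24, ct_ref_level = 21,
                          noise_sd = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(folds)) || any(!is.finite(folds)) || any(folds <= 0))
    bad_field("folds", "must be a named vector of positive finite folds")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  with_seed(substream_seed(config$seed, "qpcr"), {
    rows <- list()
    for (s in names(folds)) {
      for (g in reference_genes) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, gene = g,
          ct = ct_ref_level + stats::rnorm(1, 0, noise_sd),
          role = "reference", stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = target,
        ct = ct_target_level - log2(folds[[s]]) + stats::rnorm(1, 0, noise_sd),
        role = "target", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Evenly spaced weights within a printed range, endpoints included.
.spread <- function(lo, hi, n) if (n == 1L) lo else seq(lo, hi, length.out = n)

# Factor a target product-index value into the six D55 measurements by
# scaling a fixed realistic shape vector; preserves the product exactly.
.exam_from_product <- function(fetus_id, product) {
  shape <- .d55_base_shape[c("AD", "AH", "TD", "TH", "CRL", "HL")]
  scale <- (product / prod(shape))^(1 / 6)
  m <- shape * scale
  data.frame(fetus_id = fetus_id, day = 55L,
             AD = m[["AD"]], AH = m[["AH"]], TD = m[["TD"]], TH = m[["TH"]],
             CRL = m[["CRL"]], HL = m[["HL"]], BPD = .d55_base_shape[["BPD"]],
             stringsAsFactors = FALSE)
}

#' Deterministic study fixture cohorts
#'
#' Reconstructs the collected cohorts from the published subgroup sizes and
#' weight ranges (weights evenly spaced within each printed range, endpoints
#' included) together with the published sex-specific 97th-percentile
#' thresholds. D55 ultrasound exams are a synthetic reconstruction: each
#' fetus receives a product-index value consistent with the published
#' control maxima (91.32 at D56, 79.92 at D105) and with which fetuses
#' exceeded them (only the heaviest D56 IVP male; only the two extreme D105
#' fetuses, 986 g and 1080 g), factored into six realistic measurements.
#' Raw per-animal data were not published; the fixture reproduces the
#' printed classification counts while being transparently synthetic.
#'
#' @param day Collection day, 56 or 105.
#' @return List with `fetuses`, `exams`, and `thresholds` (named numeric,
#'   grams: the published sex-specific values).
#' @export
study_fixture <- function(day) {
  if (!day %in% c(56, 105)) bad_field("day", "must be 56 or 105")
  mk <- function(prefix, group, sex, w, twin = FALSE, ids = NULL) {
    n <- length(w)
    data.frame(
      fetus_id = if (is.null(ids)) sprintf("%s_%02d", prefix, seq_len(n)) else ids,
      dam_id = if (is.null(ids)) sprintf("%s_dam%02d", prefix, seq_len(n)) else paste0("dam_", ids),
      group = group, sex = sex, day = day, weight_g = w, twin = twin,
      stringsAsFactors = FALSE)
  }
  if (day == 56) {
    fet <- rbind(
      mk("AI_M", "AI", "M", .spread(6.21, 10.27, 8)),
      mk("AI_F", "AI", "F", .spread(6.20, 10.22, 6)),
      mk("IVPN_M", "IVP", "M", .spread(6.94, 9.98, 13)),
      mk("IVPL_M", "IVP", "M", .spread(10.23, 13.77, 8)),
      mk("IVPN_F", "IVP", "F", .spread(5.55, 9.80, 21)),
      mk("IVPL_F", "IVP", "F", 10.31, ids = "678B"))
    thresholds <- c(M = 10.18, F = 10.16)
    # Control products up to the published maximum 91.32; only the heaviest
    # IVP fetus (male, 13.77 g) exceeds the 100 line.
    prods <- numeric(nrow(fet))
    names(prods) <- fet$fetus_id
    ai <- fet$group == "AI"
    prods[ai] <- .spread(60, 91.32, sum(ai))
    ivp <- !ai
    prods[ivp] <- .spread(55, 96, sum(ivp))
    heaviest <- fet$fetus_id[which.max(replace(fet$weight_g, ai, -Inf))]
    prods[heaviest] <- 104
  } else {
    fet <- rbind(
      mk("AI_M", "AI", "M", .spread(442, 550, 8)),
      mk("AI_F", "AI", "F", .spread(388, 468, 4)),
      mk("IVPN_M", "IVP", "M", .spread(366, 542, 25)),
      mk("IVPL_M", "IVP", "M", .spread(552, 1080, 8)[1:7], ids = sprintf("IVPL_M_%02d", 1:7)),
      mk("IVPL_M2", "IVP", "M", 1080, ids = "664"),
      mk("IVPN_F", "IVP", "F", .spread(318, 448, 4)),
      mk("IVPL_F", "IVP", "F", .spread(468, 986, 9)[1:8], ids = sprintf("IVPL_F_%02d", 1:8)),
      mk("IVPL_F2", "IVP", "F", 986, ids = "604B"))
    thresholds <- c(M = 548.92, F = 463.14)
    prods <- numeric(nrow(fet))
    names(prods) <- fet$fetus_id
    ai <- fet$group == "AI"
    prods[ai] <- .spread(58, 79.92, sum(ai))
    ivp <- !ai & !fet$fetus_id %in% c("664", "604B")
    # non-extreme IVP fetuses were on or below the control-max threshold
    prods[ivp] <- .spread(52, 79.92, sum(ivp))
    prods["604B"] <- 105.8
    prods["664"] <- 117.6
  }
  exams <- do.call(rbind, lapply(seq_len(nrow(fet)), function(i)
    .exam_from_product(fet$fetus_id[i], prods[[i]])))
  rownames(exams) <- NULL
  rownames(fet) <- NULL
  list(fetuses = fet, exams = exams, thresholds = thresholds)
}
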