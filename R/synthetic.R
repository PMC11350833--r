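phylum_defaults <- function() {
  # read-abundance targets for the core equine hindgut community; the six
  # named phyla carry 92% of reads, the remainder is spread over minor phyla
  # each below 1%
  abundance <- c(
    Firmicutes        = 0.487,
    Bacteroidota      = 0.225,
    Verrucomicrobiota = 0.123,
    Spirochaetota     = 0.042,
    Fibrobacterota    = 0.031,
    Actinobacteriota  = 0.012,
    Proteobacteria    = 0.009,
    Planctomycetota   = 0.009,
    Cyanobacteria     = 0.009,
    Patescibacteria   = 0.008,
    Desulfobacterota  = 0.008,
    Elusimicrobiota   = 0.008,
    Kiritimatiellaeota = 0.008,
    Chloroflexi       = 0.008,
    Synergistota      = 0.006,
    Euryarchaeota     = 0.007
  )
  # OTU-count proportions chosen so the Firmicutes:Bacteroidota OTU-count
  # ratio is 1080/400 = 2.7
  otu_share <- c(
    Firmicutes        = 0.540,
    Bacteroidota      = 0.200,
    Verrucomicrobiota = 0.080,
    Spirochaetota     = 0.040,
    Fibrobacterota    = 0.030,
    Actinobacteriota  = 0.030,
    Proteobacteria    = 0.008,
    Planctomycetota   = 0.008,
    Cyanobacteria     = 0.008,
    Patescibacteria   = 0.008,
    Desulfobacterota  = 0.008,
    Elusimicrobiota   = 0.008,
    Kiritimatiellaeota = 0.008,
    Chloroflexi       = 0.008,
    Synergistota      = 0.008,
    Euryarchaeota     = 0.008
  )
  list(abundance = abundance, otu_share = otu_share)
}

family_pools <- function() {
  list(
    Firmicutes = c("Lachnospiraceae", "Oscillospiraceae", "Clostridiaceae",
                   "Lactobacillaceae", "Christensenellaceae"),
    Bacteroidota = c("Prevotellaceae", "Rikenellaceae", "F082",
                     "Bacteroidaceae"),
    Verrucomicrobiota = c("WCHB1-41", "Kiritimatiellaceae"),
    Spirochaetota = c("Spirochaetaceae"),
    Fibrobacterota = c("Fibrobacteraceae"),
    Actinobacteriota = c("Bifidobacteriaceae", "Coriobacteriaceae")
  )
}

#' Synthetic cohort configuration
#'
#' Parameters of the Dirichlet-multinomial cohort generator, calibrated to
#' the composition and cohort structure the analyses assume: three study
#' groups (27 control, 30 survey IBD, 19 acute IBD), 2,000 OTUs across 16
#' phyla with Firmicutes at 48.7% of reads, Bacteroidota at 22.5% and a
#' Firmicutes:Bacteroidota OTU-count ratio of 2.7, per-sample depths uniform
#' on 24,000-60,000 reads, 100 differentially abundant (DA) OTUs whose
#' phylum membership is biased towards Bacteroidota (target DA F:B count
#' ratio 0.65), correlated log2 fold changes between the two IBD groups, and
#' a negative age effect on the Firmicutes share calibrated so
#' corr(age, log10 F/B) is about -0.28.
#'
#' Presets bundle the effect parameters: `"paper"` (tau = 1.5, rho = 0.424;
#' the default), `"strong"` (tau = 2, rho = 0.95) and `"null"` (tau = 0).
#'
#' @param preset `"paper"`, `"strong"` or `"null"`.
#' @param group_sizes Named sizes of the control / survey IBD / acute IBD
#'   groups.
#' @param n_otus Number of OTUs.
#' @param phylum_abundance,phylum_otu_share Named phylum targets (read share
#'   and OTU-count share); each must sum to 1.
#' @param sigma_log Within-phylum lognormal spread of base OTU weights
#'   (natural-log SD).
#' @param theta Dirichlet concentration controlling inter-sample
#'   compositional variability (larger = less overdispersion).
#' @param depth_range Integer range of per-sample sequencing depths.
#' @param n_da Number of DA OTUs.
#' @param da_fb_ratio Target Firmicutes:Bacteroidota OTU-count ratio among
#'   the DA set.
#' @param da_min_share,da_max_share Base relative-abundance band from which
#'   DA OTUs are drawn. The lower bound keeps the effects detectable at the
#'   simulated depths; the upper bound keeps any single OTU from dominating
#'   the count-scale difference vectors, so the concordance correlation
#'   averages over many OTUs rather than a handful of dominant ones.
#' @param tau SD of the DA log2 fold changes.
#' @param rho Correlation of the survey and acute log2 fold changes.
#' @param age_range Age range in years.
#' @param age_slope Multiplicative age tilt on Firmicutes OTUs per year
#'   (negative = Firmicutes declines with age).
#' @param missing_age,missing_gender,missing_bcs Missingness rates.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(preset = c("paper", "strong", "null"),
                             group_sizes = c(control = 27, survey_ibd = 30,
                                             acute_ibd = 19),
                             n_otus = 2000,
                             phylum_abundance = phylum_defaults()$abundance,
                             phylum_otu_share = phylum_defaults()$otu_share,
                             sigma_log = 1.2,
                             theta = 5000,
                             depth_range = c(24000, 60000),
                             n_da = 100,
                             da_fb_ratio = 0.65,
                             da_min_share = 7e-4,
                             da_max_share = 1.4e-3,
                             tau = NULL,
                             rho = NULL,
                             age_range = c(2, 22),
                             age_slope = -0.0022,
                             missing_age = 0.05,
                             missing_gender = 0.05,
                             missing_bcs = 0.10) {
  preset <- match.arg(preset)
  bundle <- switch(preset,
                   paper = list(tau = 1.5, rho = 0.424),
                   strong = list(tau = 2, rho = 0.95),
                   null = list(tau = 0, rho = 0))
  if (is.null(tau)) tau <- bundle$tau
  if (is.null(rho)) rho <- bundle$rho
  stopifnot(abs(sum(phylum_abundance) - 1) < 1e-8,
            abs(sum(phylum_otu_share) - 1) < 1e-8,
            rho >= -1, rho <= 1, tau >= 0, all(group_sizes >= 1),
            identical(names(phylum_abundance), names(phylum_otu_share)))
  structure(list(preset = preset, group_sizes = group_sizes, n_otus = n_otus,
                 phylum_abundance = phylum_abundance,
                 phylum_otu_share = phylum_otu_share, sigma_log = sigma_log,
                 theta = theta, depth_range = depth_range, n_da = n_da,
                 da_fb_ratio = da_fb_ratio, da_min_share = da_min_share,
                 da_max_share = da_max_share,
                 tau = tau, rho = rho, age_range = age_range,
                 age_slope = age_slope, missing_age = missing_age,
                 missing_gender = missing_gender, missing_bcs = missing_bcs),
            class = "synthetic_config")
}

#' Default synthetic cohort configuration
#'
#' The calibrated defaults (preset `"paper"`); see [synthetic_config()].
#'
#' @return A `synthetic_config`.
#' @export
default_config <- function() synthetic_config("paper")

#' Stratified bivariate-normal effect cloud
#'
#' Deterministic low-discrepancy sample of n standard bivariate normal pairs
#' with sample correlation exactly `rho`: the first margin uses stratified
#' normal scores, the second a golden-ratio Kronecker sequence orthogonalised
#' against the first, both standardised to sample mean 0 and SD 1. Every
#' cohort therefore carries the same effect-size profile with the configured
#' correlation realised exactly, and only the assignment of effect pairs to
#' OTUs is random -- a variance-reduction choice that makes the generator's
#' calibration targets reproducible instead of hostage to a lucky draw of
#' 100 effect sizes.
#'
#' @param n Number of pairs (>= 3).
#' @param rho Target sample correlation.
#' @return An n x 2 matrix of standardised effect scores.
#' @keywords internal
effect_cloud <- function(n, rho) {
  if (n < 3) stop("need at least 3 differentially abundant OTUs")
  u <- (seq_len(n) - 0.5) / n
  v <- (seq_len(n) * (sqrt(5) - 1) / 2) %% 1
  z1 <- stats::qnorm(u)
  e <- stats::qnorm(pmin(pmax(v, 1e-12), 1 - 1e-12))
  std <- function(x) (x - mean(x)) / stats::sd(x)
  z1 <- std(z1)
  e_orth <- std(e - z1 * sum(e * z1) / sum(z1 * z1) - mean(e))
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * e_orth)
}

# Deterministic leverage-balancing assignment of effect pairs to DA OTUs:
# the largest effects go to the smallest abundance rungs (anti-monotone
# coupling), so each DA OTU contributes a comparable abundance-weighted
# effect and no handful of OTUs dominates the count-scale difference
# vectors. The (abundance x effect) design of the DA block is thereby a
# design constant of the generator, while which OTUs (and phyla) host the
# design remains random.
assign_effect_pairs <- function(b_da, z, tau) {
  v <- (1 - 2^(tau * z[, 1]))^2 + (1 - 2^(tau * z[, 2]))^2
  perm <- integer(length(b_da))
  perm[order(b_da)] <- order(v, decreasing = TRUE)
  perm
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(g)
  if (s <= 0) {
    # degenerate protection for extremely small alphas: all mass on the max
    g[which.max(alpha)] <- 1
    s <- 1
  }
  g / s
}

draw_da_set <- function(phylum, eligible, cfg, base) {
  # allocate DA quota over phyla: F and B fixed by the target DA F:B count
  # ratio, the rest proportional to the eligible pools of the other phyla
  n_b <- round(cfg$n_da * 0.40)
  n_f <- round(n_b * cfg$da_fb_ratio)
  pools <- split(which(eligible), phylum[eligible])
  quota <- c(Firmicutes = n_f, Bacteroidota = n_b)
  other <- setdiff(names(pools), names(quota))
  n_rest <- cfg$n_da - n_f - n_b
  rest_sizes <- lengths(pools[other])
  if (length(other) > 0 && n_rest > 0) {
    alloc <- round(n_rest * rest_sizes / sum(rest_sizes))
    # fix rounding drift on the largest pool
    alloc[which.max(alloc)] <- alloc[which.max(alloc)] + n_rest - sum(alloc)
    quota <- c(quota, alloc)
  }
  # draws concentrate towards the centre of the eligibility band so no
  # single DA OTU dominates the count-scale difference vectors
  centre <- sqrt(cfg$da_min_share * cfg$da_max_share)
  half_width <- log(cfg$da_max_share / centre)
  da <- integer(0)
  for (ph in names(quota)) {
    pool <- pools[[ph]]
    take <- min(quota[[ph]], length(pool))
    if (take < quota[[ph]])
      warning("eligible pool for phylum ", ph, " smaller than its DA quota")
    if (take > 0) {
      w <- pmax(1 - abs(log(base[pool] / centre)) / half_width, 0.1)^3
      da <- c(da, pool[sample.int(length(pool), take, prob = w)])
    }
  }
  sort(da)
}

#' Generate a synthetic OTU cohort with ground truth
#'
#' Builds an OTU count table, taxonomy, sample metadata and ground truth
#' with the statistical structure the analyses assume: (1) OTUs are assigned
#' to phyla by the configured count proportions; (2) within-phylum base
#' weights are drawn lognormally and rescaled so each phylum's total read
#' share equals its target exactly; (3) a DA set is drawn from the
#' detectably abundant OTUs with the configured phylum bias, with bivariate
#' normal log2 fold changes (SD `tau`, correlation `rho`); (4) each IBD
#' group's composition multiplies the DA OTUs by `2^delta` and renormalises;
#' (5) each sample draws a composition from Dirichlet(theta x group
#' composition) after tilting Firmicutes members by the sample's age, then
#' draws counts from a multinomial at a uniformly drawn depth; (6) metadata
#' receive missing values at the configured rates (biology uses the true
#' covariates).
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; the entire cohort is reproducible from it.
#' @return List with `counts` (samples x OTUs), `taxonomy`
#'   (a `taxonomy_table`), `metadata` (data frame) and `truth` (list with
#'   `da_ids`, `delta` matrix of log2 fold changes, `group`, `base_composition`,
#'   `age_true`, `config`).
#' @export
generate_cohort <- function(cfg = default_config(), seed = 1) {
  set.seed(seed)
  n_otus <- cfg$n_otus
  phyla <- names(cfg$phylum_abundance)
  n_per <- round(cfg$phylum_otu_share * n_otus)
  n_per[1] <- n_per[1] + n_otus - sum(n_per)  # absorb rounding drift
  phylum <- rep(phyla, n_per)
  otu_ids <- sprintf("otu%04d", seq_len(n_otus))

  # base composition: lognormal within phylum, phylum totals exact
  w <- stats::rlnorm(n_otus, 0, cfg$sigma_log)
  base <- numeric(n_otus)
  for (ph in phyla) {
    sel <- phylum == ph
    base[sel] <- w[sel] / sum(w[sel]) * cfg$phylum_abundance[[ph]]
  }

  # DA set and correlated effects
  eligible <- base >= cfg$da_min_share & base <= cfg$da_max_share
  da <- draw_da_set(phylum, eligible, cfg, base)
  # fixed log-spaced abundance ladder over the eligibility band for the DA
  # set (rank order preserved; phylum totals restored on the non-DA
  # members): the abundance profile of the DA OTUs is then a design
  # constant, so the calibration targets do not drift with the luck of the
  # lognormal draw
  ladder <- exp(seq(log(cfg$da_min_share), log(cfg$da_max_share),
                    length.out = length(da)))
  base[da[order(base[da])]] <- ladder
  for (ph in unique(phylum[da])) {
    sel <- phylum == ph
    da_sel <- intersect(which(sel), da)
    non_da <- setdiff(which(sel), da)
    spare <- cfg$phylum_abundance[[ph]] - sum(base[da_sel])
    if (spare <= 0 || length(non_da) == 0)
      stop("DA quota exhausts phylum '", ph, "'; lower n_da or the DA band")
    base[non_da] <- base[non_da] / sum(base[non_da]) * spare
  }
  z <- effect_cloud(length(da), cfg$rho)
  perm <- assign_effect_pairs(base[da], z, cfg$tau)
  delta <- cbind(survey_ibd = cfg$tau * z[perm, 1],
                 acute_ibd = cfg$tau * z[perm, 2])
  rownames(delta) <- otu_ids[da]

  # renormalise within the DA block: the DA OTUs keep their joint base mass,
  # so effects redistribute reads among the DA set and every non-DA OTU is
  # exactly null between groups. The realised log2 fold changes (after the
  # mass-preserving rescale) are what the truth records.
  comp <- list(control = base)
  for (grp in c("survey_ibd", "acute_ibd")) {
    v <- base
    v[da] <- v[da] * 2^delta[, grp]
    if (sum(v[da]) <= 0) stop("renormalisation failure: all-zero composition")
    scale_g <- sum(base[da]) / sum(v[da])
    v[da] <- v[da] * scale_g
    delta[, grp] <- delta[, grp] + log2(scale_g)
    comp[[grp]] <- v / sum(v)
  }

  # samples and metadata (true covariates drive the biology)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- length(groups)
  sample_ids <- sprintf("s%03d", seq_len(n))
  age_true <- round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]), 1)
  gender_true <- sample(c("mare", "gelding_stallion"), n, replace = TRUE)
  bcs_true <- sample(seq(1.5, 4.5, by = 0.5), n, replace = TRUE,
                     prob = c(1, 2, 4, 6, 4, 2, 1))

  is_f <- phylum == "Firmicutes"
  mid_age <- mean(cfg$age_range)
  depths <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n,
                   replace = TRUE)
  counts <- matrix(0L, n, n_otus, dimnames = list(sample_ids, otu_ids))
  for (i in seq_len(n)) {
    ci <- comp[[groups[i]]]
    tilt <- ci
    tilt[is_f] <- tilt[is_f] * exp(cfg$age_slope * (age_true[i] - mid_age))
    tilt <- tilt / sum(tilt)
    p_i <- rdirichlet1(cfg$theta * tilt)
    counts[i, ] <- as.integer(stats::rmultinom(1, depths[i], p_i))
  }

  # taxonomy with family assignments for the major phyla
  fams <- family_pools()
  family <- character(n_otus)
  for (ph in phyla) {
    sel <- phylum == ph
    pool <- fams[[ph]]
    family[sel] <- if (is.null(pool)) "" else sample(pool, sum(sel), replace = TRUE)
  }
  lineage <- ifelse(family == "",
                    paste0("d__Bacteria;p__", phylum),
                    paste0("d__Bacteria;p__", phylum, ";c__;o__;f__", family))
  taxonomy <- taxonomy_table(otu_ids, lineage)

  metadata <- data.frame(sample_id = sample_ids, status = groups,
                         age = age_true, gender = gender_true, bcs = bcs_true,
                         stringsAsFactors = FALSE)
  metadata$age[stats::runif(n) < cfg$missing_age] <- NA
  metadata$gender[stats::runif(n) < cfg$missing_gender] <- NA
  metadata$bcs[stats::runif(n) < cfg$missing_bcs] <- NA
  metadata <- validate_metadata(metadata)

  truth <- list(da_ids = otu_ids[da], delta = delta, group = groups,
                base_composition = stats::setNames(base, otu_ids),
                phylum = stats::setNames(phylum, otu_ids),
                age_true = age_true, depths = depths, config = cfg)
  list(counts = counts, taxonomy = taxonomy, metadata = metadata,
       truth = truth)
}
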