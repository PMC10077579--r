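# Synthetic lake-survey generator. Produces per-lake peak lists and an
# environment table with known ground truth, emulating the processes the
# analysis is meant to detect: evapo-concentration/photodegradative loss
# of aromatics along the conductivity gradient, sulfurization in
# hypersaline lakes, N-enrichment in proglacial meltwater lakes, and
# spatial coordinates drawn independently of composition. The generator is
# phenomenological: mechanisms act as inclusion-probability modifiers on a
# shared formula pool, not as reaction kinetics.

#' Survey generator configuration
#'
#' @param n_lakes number of lakes.
#' @param lake_type_mix proportions of the four lake types (sums to 1).
#' @param pool_sizes formulas per source class: `fresh` (H/C >= 1.5,
#'   N-bearing), `highly_unsaturated` (AI_mod <= 0.5, H/C < 1.5) and
#'   `aromatic` (AI_mod > 0.5).
#' @param base_rate baseline inclusion probability of a pool formula in a
#'   lake.
#' @param degradation_strength coefficient linking z-scored log10 EC to
#'   the removal of aromatic (high AI_mod) formulas.
#' @param z_saturation cap on the effective z-scored log10 EC in the
#'   removal term: once the photodegradable aromatic stock is exhausted,
#'   further evapo-concentration removes little more.
#' @param ph_penalty additional removal rate of O-rich aromatics per pH
#'   unit above 7.
#' @param fresh_boost multiplicative up-weighting of the fresh class in
#'   proglacial lakes.
#' @param sulfurization_fraction fraction of the pool converted to
#'   S-bearing analogs (one O swapped for one S) in hypersaline lakes.
#' @param n_enrichment_fraction fraction of the fresh class occurring
#'   exclusively in proglacial lakes.
#' @param intensity_meanlog,intensity_sdlog lognormal intensity
#'   parameters.
#' @param mass_error_ppm Gaussian m/z jitter (ppm).
#' @param mass_range neutral-mass window of the pool (Da).
#' @param log_ec_center,log_ec_scale fallback centring/scaling of log10 EC
#'   used when a lake is generated outside a survey (inside
#'   [generate_survey()] the realised survey values are used).
#' @param seed integer seed (mandatory).
#' @return Object of class `survey_config`.
#' @export
survey_config <- function(n_lakes = 40,
                          lake_type_mix = c(
                            proglacial = 0.25, freshwater = 0.35,
                            saline = 0.20, hypersaline = 0.20
                          ),
                          pool_sizes = c(
                            fresh = 2700, highly_unsaturated = 3100,
                            aromatic = 1500
                          ),
                          base_rate = 0.35,
                          degradation_strength = 1.4,
                          z_saturation = 2,
                          ph_penalty = 0.6,
                          fresh_boost = 1.8,
                          sulfurization_fraction = 0.08,
                          n_enrichment_fraction = 0.20,
                          intensity_meanlog = 16,
                          intensity_sdlog = 1,
                          mass_error_ppm = 0.2,
                          mass_range = c(150, 700),
                          log_ec_center = -0.7,
                          log_ec_scale = 1.3,
                          seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  types <- c("proglacial", "freshwater", "saline", "hypersaline")
  if (!setequal(names(lake_type_mix), types)) {
    stop("lake_type_mix must name all four lake types", call. = FALSE)
  }
  if (abs(sum(lake_type_mix) - 1) > 1e-9) stop("lake_type_mix must sum to 1", call. = FALSE)
  stopifnot(
    n_lakes >= 4, all(pool_sizes > 0), base_rate > 0, base_rate <= 1,
    degradation_strength >= 0, sulfurization_fraction >= 0,
    sulfurization_fraction <= 1, n_enrichment_fraction >= 0,
    n_enrichment_fraction <= 1, mass_error_ppm >= 0
  )
  structure(
    list(
      n_lakes = n_lakes, lake_type_mix = lake_type_mix[types],
      pool_sizes = pool_sizes, base_rate = base_rate,
      degradation_strength = degradation_strength,
      z_saturation = z_saturation, ph_penalty = ph_penalty,
      fresh_boost = fresh_boost,
      sulfurization_fraction = sulfurization_fraction,
      n_enrichment_fraction = n_enrichment_fraction,
      intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog,
      mass_error_ppm = mass_error_ppm, mass_range = mass_range,
      log_ec_center = log_ec_center, log_ec_scale = log_ec_scale,
      seed = as.integer(seed)
    ),
    class = "survey_config"
  )
}

# Draws one source class by rejection until `size` distinct, chemically
# valid formulas inside the mass window are found.
draw_class <- function(class, size, cfg, acfg) {
  got <- list()
  seen <- character()
  attempts <- 0L
  max_attempts <- 400L * size
  while (length(got) < size && attempts < max_attempts) {
    n <- (size - length(got)) * 4L
    attempts <- attempts + n
    cand <- switch(class,
      fresh = {
        C <- sample(8:30, n, replace = TRUE)
        N <- sample(1:4, n, replace = TRUE)
        H <- round(C * stats::runif(n, 1.5, 2.15))
        O <- round(C * stats::runif(n, 0.15, 0.8))
        data.frame(C = C, H = H, N = N, O = O, S = 0L, P = 0L)
      },
      aromatic = {
        C <- sample(10:36, n, replace = TRUE)
        N <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
        H <- round(C * stats::runif(n, 0.35, 1.0))
        O <- round(C * stats::runif(n, 0.05, 0.55))
        data.frame(C = C, H = H, N = N, O = O, S = 0L, P = 0L)
      },
      highly_unsaturated = {
        C <- sample(10:35, n, replace = TRUE)
        N <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
        H <- round(C * stats::runif(n, 0.95, 1.45))
        O <- round(C * stats::runif(n, 0.2, 0.85))
        data.frame(C = C, H = H, N = N, O = O, S = 0L, P = 0L)
      },
      stop("unknown class: ", class, call. = FALSE)
    )
    # even-electron parity: H + N + P must be even
    odd <- (cand$H + cand$N) %% 2 == 1
    cand$H[odd] <- cand$H[odd] + 1L
    cand <- cand[cand$H >= 1, , drop = FALSE]
    cand <- apply_chemical_filters(cand, acfg)
    if (nrow(cand) == 0) next
    mass <- formula_mass(cand)
    cand <- cand[mass >= cfg$mass_range[1] & mass <= cfg$mass_range[2], , drop = FALSE]
    if (nrow(cand) == 0) next
    cls <- classify_formula(cand)$category
    hc <- cand$H / cand$C
    ok <- switch(class,
      fresh = hc >= 1.5,
      aromatic = cls == "aromatic",
      highly_unsaturated = cls == "highly_unsaturated"
    )
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) next
    key <- formula_string(cand)
    new <- !duplicated(key) & !(key %in% seen)
    cand <- cand[new, , drop = FALSE]
    if (nrow(cand) == 0) next
    seen <- c(seen, formula_string(cand))
    got[[length(got) + 1L]] <- cand
  }
  pool <- do.call(rbind, got)
  if (is.null(pool) || nrow(pool) < size) {
    stop("infeasible class constraints for '", class, "' after ", max_attempts,
      " attempts",
      call. = FALSE
    )
  }
  pool <- pool[seq_len(size), , drop = FALSE]
  pool$class <- class
  pool
}

#' Generate the labelled formula pool of a survey
#'
#' Three source classes are drawn inside community-standard element
#' ranges: a fresh, H-rich, N-bearing class typical of microbial-derived
#' material; a humic-like aromatic class (AI_mod > 0.5); and a highly
#' unsaturated backbone class. The ten degradation-index reference
#' formulas are appended as a `reference` class. Every formula passes the
#' assignment module's chemical filters; class labels, proglacial-marker
#' and sulfurizable flags are retained as ground truth.
#'
#' @param cfg a [survey_config()].
#' @param seed integer seed.
#' @return Data frame: element counts, `formula`, `mass`, `class`,
#'   `proglacial_marker`, `sulfurizable`, `s_analog` (canonical string of
#'   the O->S analog, or `NA`).
#' @export
generate_formula_pool <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  acfg <- assignment_config()
  pool <- rbind(
    draw_class("fresh", cfg$pool_sizes[["fresh"]], cfg, acfg),
    draw_class("highly_unsaturated", cfg$pool_sizes[["highly_unsaturated"]], cfg, acfg),
    draw_class("aromatic", cfg$pool_sizes[["aromatic"]], cfg, acfg)
  )
  ref <- ideg_reference_sets()
  ref_tab <- rbind(ref$neg, ref$pos)
  ref_tab$class <- "reference"
  # reference rows first so the duplicate pass cannot displace them
  pool <- rbind(ref_tab[names(pool)], pool)
  pool$formula <- formula_string(pool)
  pool$mass <- formula_mass(pool)
  # avoid near-isobaric twins that would violate the peak-list 0.1 mDa rule
  pool <- pool[!duplicated(round(pool$mass, 4)), , drop = FALSE]
  pool <- pool[order(pool$mass), , drop = FALSE]
  rownames(pool) <- NULL

  # proglacial markers: the most aliphatic, N-rich end of the fresh class
  # (lowest DBE_AI) -- freshly produced proteinaceous material that only
  # persists in the short-residence meltwater lakes
  pool$proglacial_marker <- FALSE
  fresh_idx <- which(pool$class == "fresh")
  n_mark <- round(cfg$n_enrichment_fraction * length(fresh_idx))
  if (n_mark > 0) {
    low_dbe_ai <- fresh_idx[order(dbe_ai(pool[fresh_idx, ]))[seq_len(n_mark)]]
    pool$proglacial_marker[low_dbe_ai] <- TRUE
  }

  # sulfurization targets the most unsaturated, O-bearing cores (quinone-
  # like moieties react readily with sulfide), so the sulfurizable subset
  # is drawn from the high-DBE_AI end of the pool
  pool$sulfurizable <- FALSE
  pool$s_analog <- NA_character_
  eligible <- which(pool$O >= 1 & pool$S == 0 & pool$class != "reference" &
    !pool$proglacial_marker)
  n_sulf <- round(cfg$sulfurization_fraction * nrow(pool))
  if (n_sulf > 0) {
    cand <- eligible[order(-dbe_ai(pool[eligible, ]))[seq_len(min(n_sulf, length(eligible)))]]
    analog <- pool[cand, ELEMENTS]
    analog$O <- analog$O - 1L
    analog$S <- analog$S + 1L
    amass <- formula_mass(analog)
    akey <- formula_string(analog)
    filtered <- apply_chemical_filters(analog, assignment_config())
    ok <- akey %in% formula_string(filtered) &
      !(akey %in% pool$formula) &
      !(round(amass, 4) %in% round(pool$mass, 4)) &
      amass <= cfg$mass_range[2] + 20
    pool$sulfurizable[cand[ok]] <- TRUE
    pool$s_analog[cand[ok]] <- akey[ok]
  }
  pool
}

#' Generate one lake's peak list from the pool
#'
#' Inclusion probability of a pool formula is
#' `base_rate * exp(-degradation_strength * z(log10 EC) * max(AI_mod, 0))`
#' (capped at 1), with an additional pH penalty for O-rich aromatics.
#' Proglacial lakes up-weight the fresh class and are the only lakes
#' containing the proglacial marker formulas; hypersaline lakes emit the
#' sulfurizable subset as O->S analogs. Intensities are lognormal and
#' observed m/z values are [M-H]- masses with Gaussian ppm jitter.
#'
#' @param pool data frame from [generate_formula_pool()].
#' @param env_row one-row data frame with `lake_id`, `lake_type`, `EC`,
#'   `pH` and optionally `z_log_ec` (supplied by [generate_survey()];
#'   otherwise computed from `cfg$log_ec_center` and `cfg$log_ec_scale`).
#' @param cfg a [survey_config()].
#' @param seed integer seed.
#' @return A [peaklist()].
#' @export
generate_lake <- function(pool, env_row, cfg, seed) {
  stopifnot(all(c("lake_type", "EC", "pH") %in% names(env_row)))
  set.seed(seed)
  z <- if (!is.null(env_row$z_log_ec)) {
    env_row$z_log_ec
  } else {
    (log10(env_row$EC) - cfg$log_ec_center) / cfg$log_ec_scale
  }
  type <- as.character(env_row$lake_type)
  ai <- ai_mod(pool)
  w <- pmax(ai, 0)
  z_eff <- min(z, cfg$z_saturation)
  p <- cfg$base_rate * exp(-cfg$degradation_strength * z_eff * w)
  cls <- classify_formula(pool)
  o_rich_aromatic <- cls$category == "aromatic" & pool$O / pool$C >= 0.5
  p[o_rich_aromatic] <- p[o_rich_aromatic] *
    exp(-cfg$ph_penalty * max(env_row$pH - 7, 0))
  if (type == "proglacial") {
    p[pool$class == "fresh"] <- p[pool$class == "fresh"] * cfg$fresh_boost
  }
  p[pool$proglacial_marker] <- if (type == "proglacial") 0.95 else 0
  # sulfide-rich brines both form and preserve the sulfurized compounds,
  # so their precursors accumulate reliably in hypersaline lakes
  if (type == "hypersaline") p[pool$sulfurizable] <- 0.95
  p[pool$class == "reference"] <- 1
  p <- pmin(pmax(p, 0), 1)
  keep <- stats::runif(nrow(pool)) < p
  if (!any(keep)) stop("generated lake is empty; parameters infeasible", call. = FALSE)
  lake <- pool[keep, , drop = FALSE]

  # hypersaline sulfurization: retained sulfurizable formulas appear as
  # their S-bearing analog (one O swapped for one S)
  if (type == "hypersaline") {
    sub <- which(lake$sulfurizable)
    if (length(sub)) {
      lake$O[sub] <- lake$O[sub] - 1L
      lake$S[sub] <- lake$S[sub] + 1L
      lake$formula[sub] <- lake$s_analog[sub]
      lake$mass[sub] <- formula_mass(lake[sub, ELEMENTS])
    }
  }

  intensity <- stats::rlnorm(nrow(lake), cfg$intensity_meanlog, cfg$intensity_sdlog)
  is_ref <- lake$class == "reference"
  if (any(is_ref)) {
    ref <- ideg_reference_sets()
    neg_keys <- formula_string(ref$neg)
    scale_ref <- ifelse(lake$formula[is_ref] %in% neg_keys, 0.9, 5)
    intensity[is_ref] <- scale_ref * exp(cfg$intensity_meanlog) *
      stats::rlnorm(sum(is_ref), 0, 0.1)
  }

  # calibrated peak lists carry bounded residual errors: Gaussian jitter
  # truncated at +/- 2 sd
  jitter <- pmin(pmax(stats::rnorm(nrow(lake)), -2), 2)
  mz <- (lake$mass - PROTON_MASS) *
    (1 + jitter * cfg$mass_error_ppm * 1e-6)
  # drop the weaker of any pair closer than the 0.1 mDa duplicate limit
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  repeat {
    close <- which(diff(mz) < 1e-4)
    if (!length(close)) break
    i <- close[1]
    drop <- if (intensity[i] < intensity[i + 1]) i else i + 1L
    mz <- mz[-drop]
    intensity <- intensity[-drop]
  }
  peaklist(mz, intensity,
    sample_id = if (!is.null(env_row$lake_id)) as.character(env_row$lake_id) else "lake"
  )
}

#' Generate a complete synthetic lake survey
#'
#' Draws the environment table (EC lognormal per lake type, pH in the
#' neutral-to-basic band, DIN elevated in hypersaline lakes, DOC
#' increasing with EC, coordinates independent of everything else), the
#' formula pool, and one peak list per lake.
#'
#' @param cfg a [survey_config()].
#' @return Object of class `dom_survey`: list with `peaklists` (named
#'   list), `env` (environment table), `truth` (list: `lake_type`, `pool`,
#'   `exclusive` — data frame of planted cluster-exclusive formulas and
#'   the lake type they mark) and `config`.
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "survey_config"))
  set.seed(cfg$seed)
  types <- names(cfg$lake_type_mix)
  counts <- round(cfg$lake_type_mix * cfg$n_lakes)
  while (sum(counts) > cfg$n_lakes) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  while (sum(counts) < cfg$n_lakes) counts[which.min(counts)] <- counts[which.min(counts)] + 1
  lake_type <- rep(types, counts)

  ec_meanlog <- c(
    proglacial = log(0.01), freshwater = log(0.08),
    saline = log(2), hypersaline = log(40)
  )
  ec_sdlog <- c(
    proglacial = 0.25, freshwater = 0.25, saline = 0.2, hypersaline = 0.15
  )
  ph_mean <- c(
    proglacial = 7.4, freshwater = 7.8, saline = 8.2, hypersaline = 8.6
  )
  temp_mean <- c(
    proglacial = 1, freshwater = 3, saline = 5, hypersaline = 7
  )
  din_meanlog <- c(
    proglacial = log(2), freshwater = log(1), saline = log(5),
    hypersaline = log(30)
  )

  n <- cfg$n_lakes
  EC <- stats::rlnorm(n, ec_meanlog[lake_type], ec_sdlog[lake_type])
  pH <- pmin(pmax(stats::rnorm(n, ph_mean[lake_type], 0.2), 7.1), 8.9)
  temp <- stats::rnorm(n, temp_mean[lake_type], 1.5)
  DIN <- stats::rlnorm(n, din_meanlog[lake_type], 0.4)
  DOC <- 0.3 + 1.5 * EC^0.85 * stats::rlnorm(n, 0, 0.3)

  env <- data.frame(
    lake_id = sprintf("L%02d", seq_len(n)),
    lake_type = lake_type,
    latitude = stats::runif(n, -69.5, -68.9),
    longitude = stats::runif(n, 39.3, 40.2),
    EC = EC,
    pH = pH,
    water_temperature = temp,
    DIN = DIN,
    DOC = DOC
  )
  env <- validate_environment_table(env)
  env$z_log_ec <- as.vector(scale(log10(env$EC)))

  pool <- generate_formula_pool(cfg, seed = cfg$seed)
  lake_seeds <- sample.int(.Machine$integer.max - 1L, n)
  peaklists <- lapply(seq_len(n), function(i) {
    generate_lake(pool, env[i, , drop = FALSE], cfg, seed = lake_seeds[i])
  })
  names(peaklists) <- env$lake_id

  markers <- pool$formula[pool$proglacial_marker]
  analogs <- pool$s_analog[pool$sulfurizable]
  exclusive <- data.frame(
    formula = c(markers, analogs),
    lake_type = c(
      rep("proglacial", length(markers)),
      rep("hypersaline", length(analogs))
    )
  )
  structure(
    list(
      peaklists = peaklists,
      env = env,
      truth = list(
        lake_type = stats::setNames(env$lake_type, env$lake_id),
        pool = pool,
        exclusive = exclusive
      ),
      config = cfg
    ),
    class = "dom_survey"
  )
}

#' @export
print.dom_survey <- function(x, ...) {
  cat(sprintf(
    "Synthetic DOM survey: %d lakes, %d pool formulas (seed %d)\n",
    length(x$peaklists), nrow(x$truth$pool), x$config$seed
  ))
  print(table(type = x$env$lake_type))
  invisible(x)
}

#' Write a survey to disk in the formats the pipeline reads
#'
#' One peak-list CSV per lake, `environment.csv`, and a
#' `ground_truth.json` sidecar with lake types and planted markers.
#'
#' @param survey a `dom_survey`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "dom_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(survey$peaklists)) {
    write_peaklist(survey$peaklists[[id]], file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(survey$env, file.path(dir, "environment.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      lake_type = as.list(stats::setNames(
        as.character(survey$truth$lake_type), names(survey$truth$lake_type)
      )),
      exclusive = survey$truth$exclusive,
      pool_class = as.list(stats::setNames(
        survey$truth$pool$class, survey$truth$pool$formula
      ))
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
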