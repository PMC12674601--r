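#' Search space for circuit fitting
#'
#' @param name parameter names understood by [apply_params()]:
#'   `"counts.OLM"` / `"counts.basket"` / `"counts.pyramidal"` (integer
#'   cell counts), `"<olm|basket|pyr>.<param>"` membrane parameters (e.g.
#'   `"pyr.gNaP"`), `"drive.I_app_mean.<type>"` and
#'   `"drive.I_app_noise_sd.<type>"` drive parameters,
#'   `"syn.<pre>.<post>"` projection weights, and `"nap_scale"` (common
#'   multiplier on all persistent-Na conductances).
#' @param lower,upper bounds, `lower < upper`.
#' @param integer logical; integer-valued parameters (cell counts) are
#'   rounded and searched on the integer lattice.
#' @param stage `"control"` (drives, conductances, connectivity) or
#'   `"mutant"` (persistent-Na strengths and cell counts only).
#' @return a `"parameter_space"` data frame.
#' @export
parameter_space <- function(name, lower, upper, integer = FALSE,
                            stage = c("control", "mutant")) {
  stage <- match.arg(stage)
  if (any(lower >= upper)) stop("need lower < upper for every entry")
  integer <- rep_len(integer, length(name))
  if (stage == "mutant") {
    ok <- grepl("^counts\\.", name) | grepl("\\.gNaP$", name) |
      name == "nap_scale"
    if (!all(ok))
      stop("mutant stage may only search cell counts and persistent-Na ",
           "strengths; offending: ", paste(name[!ok], collapse = ", "))
  }
  structure(data.frame(name = name, lower = lower, upper = upper,
                       integer = integer, stringsAsFactors = FALSE),
            stage = stage, class = c("parameter_space", "data.frame"))
}

#' Apply named parameter values to a circuit configuration
#'
#' @param config a [circuit_config()].
#' @param params named numeric vector using the [parameter_space()]
#'   naming scheme.
#' @return the modified `"circuit_config"`.
#' @export
apply_params <- function(config, params) {
  stopifnot(inherits(config, "circuit_config"))
  for (nm in names(params)) {
    val <- unname(params[[nm]])
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "counts") {
      i <- match(parts[2], CELL_TYPES)
      if (is.na(i)) stop("unknown cell type in ", nm)
      config$counts[i] <- as.integer(round(val))
    } else if (parts[1] %in% c("olm", "basket", "pyr")) {
      slot <- parts[1]
      if (!parts[2] %in% names(config[[slot]]))
        stop("unknown membrane parameter in ", nm)
      config[[slot]][parts[2]] <- val
    } else if (parts[1] == "drive") {
      config$drive[[parts[2]]][parts[3]] <- val
    } else if (parts[1] == "syn") {
      i <- which(config$synapses$pre_type == parts[2] &
                   config$synapses$post_type == parts[3])
      if (!length(i)) stop("no projection ", parts[2], "->", parts[3])
      config$synapses$weight[i] <- val
    } else if (nm == "nap_scale") {
      config$olm["gNaP"] <- config$olm["gNaP"] * val
      config$basket["gNaP"] <- config$basket["gNaP"] * val
      config$pyr["gNaP"] <- config$pyr["gNaP"] * val
    } else stop("unknown parameter: ", nm)
  }
  config
}

## read current values of space entries from a config (nap_scale reads 1)
current_params <- function(config, space) {
  vapply(space$name, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "counts") config$counts[match(parts[2], CELL_TYPES)]
    else if (parts[1] %in% c("olm", "basket", "pyr"))
      unname(config[[parts[1]]][parts[2]])
    else if (parts[1] == "drive") unname(config$drive[[parts[2]]][parts[3]])
    else if (parts[1] == "syn")
      config$synapses$weight[which(config$synapses$pre_type == parts[2] &
                                     config$synapses$post_type ==
                                       parts[3])[1]]
    else if (nm == "nap_scale") 1
    else stop("unknown parameter: ", nm)
  }, numeric(1))
}

#' Genetic-algorithm hyperparameters
#'
#' @param population individuals per generation (>= 4).
#' @param generations number of generations.
#' @param crossover_rate probability of uniform crossover per pair.
#' @param mutation_sd_fraction Gaussian mutation SD as a fraction of each
#'   parameter's range.
#' @param elitism number of best individuals copied unchanged.
#' @param tournament_size tournament selection size.
#' @param sim_duration_per_eval simulated seconds per evaluation.
#' @param replicates_per_eval noise replicates averaged per evaluation
#'   (>= 1); replicate seeds are fixed across individuals and
#'   generations so the fitness landscape is deterministic.
#' @param seed integer seed for the whole run.
#' @return a `"ga_config"` list.
#' @export
ga_config <- function(population = 50, generations = 100,
                      crossover_rate = 0.7, mutation_sd_fraction = 0.1,
                      elitism = 2, tournament_size = 3,
                      sim_duration_per_eval = 20,
                      replicates_per_eval = 2, seed = 1) {
  if (population < 4) stop("population must be >= 4")
  if (replicates_per_eval < 1) stop("replicates_per_eval must be >= 1")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_sd_fraction = mutation_sd_fraction,
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 sim_duration_per_eval = sim_duration_per_eval,
                 replicates_per_eval = as.integer(replicates_per_eval),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Electrophysiological feature vector of a simulation
#'
#' Theta-gamma monophasicity (per-trial median when the LFP spans at
#' least two trials, otherwise a single whole-record modulogram), theta
#' (3-10 Hz) and low-gamma (30-80 Hz) integrated band power, theta peak
#' frequency, and the theta-instability K statistic.
#'
#' @param result a `"ca3_simresult"` with an LFP of at least 10 s.
#' @param pac_cfg a [pac_config()].
#' @param chaos_cfg a [chaos_config()]; the default downsamples to
#'   100 Hz so a 10 s LFP meets the test's 1000-sample minimum.
#' @return named numeric vector: `monophasicity`, `theta_power`,
#'   `theta_peak_freq`, `theta_K`, `gamma_power`.
#' @export
extract_features <- function(result, pac_cfg = pac_config(),
                             chaos_cfg = chaos_config(downsample_to = 100,
                                                      n_c = 50)) {
  stopifnot(inherits(result, "ca3_simresult"))
  lfp <- result$lfp
  if (is.null(lfp)) stop("simulation has no LFP (no pyramidal cells)")
  if (ts_duration(lfp) < 10) stop("LFP must span at least 10 s")
  mono <- tryCatch({
    if (ts_duration(lfp) >= 2 * pac_cfg$trial_len)
      monophasicity_of_recording(lfp, pac_cfg)$overall
    else monophasicity(compute_modulogram(lfp, pac_cfg),
                       method = pac_cfg$cor_method)
  }, error = function(e) stop("monophasicity stage failed: ",
                              conditionMessage(e)))
  spec <- tryCatch(periodogram(lfp, seg_len = min(ts_duration(lfp), 5)),
                   error = function(e) stop("spectrum stage failed: ",
                                            conditionMessage(e)))
  th <- spec$freqs >= 3 & spec$freqs <= 10
  theta_peak <- spec$freqs[th][which.max(spec$power[th])]
  K <- tryCatch(theta_instability(lfp, chaos_cfg)$K,
                error = function(e) stop("instability stage failed: ",
                                         conditionMessage(e)))
  c(monophasicity = mono,
    theta_power = band_power(spec, 3, 10),
    theta_peak_freq = theta_peak,
    theta_K = K,
    gamma_power = band_power(spec, 30, 80))
}

#' Weighted fitness of a feature vector against targets
#'
#' Sum of weighted squared errors, each normalized by the target
#' magnitude (or 1 when the target is near zero). Features listed in
#' `preserve` incur a hard penalty multiplier when they deviate by more
#' than 20%, implementing constraints such as "preserve theta power"
#' during the mutant stage.
#'
#' @param fv,targets named feature vectors (see [extract_features()]).
#' @param weights named non-negative weights (default 1 for every target
#'   feature).
#' @param preserve character vector of feature names under the hard
#'   constraint.
#' @param preserve_penalty penalty multiplier (default 25).
#' @return a scalar >= 0 (0 iff `fv == targets` on all weighted
#'   features).
#' @export
fitness <- function(fv, targets, weights = NULL, preserve = character(),
                    preserve_penalty = 25) {
  nms <- names(targets)
  if (is.null(weights)) weights <- setNames(rep(1, length(nms)), nms)
  if (any(weights < 0)) stop("weights must be >= 0")
  total <- 0
  for (nm in nms) {
    denom <- max(abs(targets[[nm]]), 1e-8)
    if (abs(targets[[nm]]) < 1e-8) denom <- 1
    err <- (fv[[nm]] - targets[[nm]]) / denom
    term <- (weights[[nm]] %||% 1) * err^2
    if (nm %in% preserve && abs(err) > 0.2) term <- term * preserve_penalty
    total <- total + term
  }
  total
}

## Deterministic evaluation of one parameter vector: simulate with fixed
## replicate seeds, average features. Divergent simulations get Inf.
eval_individual <- function(theta, space, base_config, ga_cfg, pac_cfg,
                            chaos_cfg) {
  cfg <- base_config
  cfg$duration <- ga_cfg$sim_duration_per_eval
  names(theta) <- space$name
  cfg <- apply_params(cfg, theta)
  fvs <- NULL
  for (rep_i in seq_len(ga_cfg$replicates_per_eval)) {
    seed_i <- derive_seed(ga_cfg$seed, 1000L + rep_i)
    res <- tryCatch(simulate_circuit(cfg, seed = seed_i),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    fv <- tryCatch(extract_features(res, pac_cfg, chaos_cfg),
                   error = function(e) NULL)
    if (is.null(fv)) return(NULL)
    fvs <- rbind(fvs, fv)
  }
  colMeans(fvs)
}

#' Evaluate the feature vector of a parameter point
#'
#' Runs the same deterministic evaluation the GA uses (fixed replicate
#' seeds derived from the GA seed), which makes it suitable for
#' generating synthetic fitting targets from known parameters.
#'
#' @param params named parameter values ([parameter_space()] names).
#' @param base_config a [circuit_config()].
#' @param ga_cfg a [ga_config()] (supplies duration, replicates, seed).
#' @inheritParams extract_features
#' @return named feature vector, or `NULL` if the simulation diverged.
#' @export
evaluate_params <- function(params, base_config, ga_cfg,
                            pac_cfg = pac_config(),
                            chaos_cfg = chaos_config(downsample_to = 100,
                                                     n_c = 50)) {
  space <- parameter_space(names(params), unname(params) - 1e-9,
                           unname(params) + 1e-9)
  eval_individual(unname(params), space, base_config, ga_cfg, pac_cfg,
                  chaos_cfg)
}

#' Genetic-algorithm fit of circuit parameters to feature targets
#'
#' Seeded tournament selection, uniform crossover and Gaussian mutation
#' (integer parameters rounded, all clipped to bounds), with elitism
#' guaranteeing a non-increasing best-fitness trace. Each individual is
#' evaluated by simulating the circuit and extracting features, averaged
#' over noise replicates with seeds shared across all individuals (the
#' fitness landscape is deterministic given the GA seed). Individuals
#' whose simulation diverges receive worst fitness and the run
#' continues. The base configuration's own parameter values are included
#' in the initial population (clipped to bounds).
#'
#' @param space a [parameter_space()].
#' @param base_config a [circuit_config()]; parameters outside the space
#'   stay frozen at their base values.
#' @param targets named feature vector (see [extract_features()]).
#' @param ga_cfg a [ga_config()].
#' @param weights,preserve passed to [fitness()].
#' @param pac_cfg,chaos_cfg feature-extraction settings.
#' @param verbose print per-generation progress.
#' @return An object of class `"ca3_fitresult"`: `best_params`,
#'   `best_fitness`, `best_config`, `best_features`, `fitness_trace`,
#'   `feature_trace`, `seed_echo`, `space`.
#' @export
run_ga <- function(space, base_config, targets, ga_cfg = ga_config(),
                   weights = NULL, preserve = character(),
                   pac_cfg = pac_config(),
                   chaos_cfg = chaos_config(downsample_to = 100, n_c = 50),
                   verbose = FALSE) {
  stopifnot(inherits(space, "parameter_space"),
            inherits(base_config, "circuit_config"))
  d <- nrow(space)
  rng <- space$upper - space$lower
  set.seed(derive_seed(ga_cfg$seed, 7L))
  clip <- function(x) {
    x <- pmin(space$upper, pmax(space$lower, x))
    ifelse(space$integer, round(x), x)
  }
  pop <- matrix(stats::runif(ga_cfg$population * d,
                             rep(space$lower, each = ga_cfg$population),
                             rep(space$upper, each = ga_cfg$population)),
                ga_cfg$population, d)
  pop[1, ] <- current_params(base_config, space)
  pop <- t(apply(pop, 1, clip))
  if (d == 1) pop <- matrix(pop, ncol = 1)

  evaluate <- function(theta) {
    fv <- eval_individual(theta, space, base_config, ga_cfg, pac_cfg,
                          chaos_cfg)
    if (is.null(fv)) {
      warning("simulation diverged during evaluation; assigning worst fitness")
      return(list(fit = Inf, fv = NULL))
    }
    list(fit = fitness(fv, targets, weights, preserve), fv = fv)
  }

  fit <- numeric(ga_cfg$population)
  fvs <- vector("list", ga_cfg$population)
  for (i in seq_len(ga_cfg$population)) {
    e <- evaluate(pop[i, ]); fit[i] <- e$fit; fvs[[i]] <- e$fv
  }
  trace <- numeric(ga_cfg$generations)
  ftrace <- NULL
  for (gen in seq_len(ga_cfg$generations)) {
    ord <- order(fit)
    elite_idx <- ord[seq_len(ga_cfg$elitism)]
    newpop <- pop[elite_idx, , drop = FALSE]
    while (nrow(newpop) < ga_cfg$population) {
      tourn <- function() {
        cand <- sample.int(ga_cfg$population, ga_cfg$tournament_size)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[tourn(), ]; p2 <- pop[tourn(), ]
      if (stats::runif(1) < ga_cfg$crossover_rate) {
        mask <- stats::runif(d) < 0.5
        child <- ifelse(mask, p1, p2)
      } else child <- p1
      child <- child + stats::rnorm(d, 0, ga_cfg$mutation_sd_fraction * rng)
      newpop <- rbind(newpop, clip(child))
    }
    keep_fit <- fit[elite_idx]; keep_fv <- fvs[elite_idx]
    pop <- newpop
    fit <- c(keep_fit, numeric(ga_cfg$population - ga_cfg$elitism))
    fvs <- c(keep_fv, vector("list", ga_cfg$population - ga_cfg$elitism))
    for (i in (ga_cfg$elitism + 1):ga_cfg$population) {
      e <- evaluate(pop[i, ]); fit[i] <- e$fit; fvs[[i]] <- e$fv
    }
    best <- which.min(fit)
    trace[gen] <- fit[best]
    ftrace <- rbind(ftrace, fvs[[best]])
    if (verbose)
      message(sprintf("gen %d: best fitness %.4g", gen, fit[best]))
  }
  best <- which.min(fit)
  best_params <- stats::setNames(pop[best, ], space$name)
  best_config <- apply_params(base_config, best_params)
  structure(list(best_params = best_params, best_fitness = fit[best],
                 best_config = best_config, best_features = fvs[[best]],
                 fitness_trace = trace, feature_trace = ftrace,
                 seed_echo = ga_cfg$seed, space = space),
            class = "ca3_fitresult")
}

#' @export
print.ca3_fitresult <- function(x, ...) {
  cat(sprintf("<fitresult> best fitness %.4g after %d generations\n",
              x$best_fitness, length(x$fitness_trace)))
  print(round(x$best_params, 4))
  invisible(x)
}

#' Mutant-stage fit: persistent-Na strengths and cell counts only
#'
#' Second optimization stage: starting from a fitted control circuit, the
#' search space is restricted to the persistent sodium conductances of
#' all three cell types plus the cell counts; every other parameter is
#' frozen at the control optimum, and theta power is preserved (hard
#' fitness penalty beyond 20% deviation).
#'
#' @param control_fit a `"ca3_fitresult"` from the control stage (or any
#'   object with a `best_config` circuit).
#' @param targets_mut mutant feature targets.
#' @param ga_cfg a [ga_config()].
#' @param space optional [parameter_space()] override (must satisfy the
#'   mutant-stage restriction); the default searches each `gNaP` in
#'   `[0.25x, 6x]` its control value and each count within -3/+5 of the
#'   control (floor 1).
#' @param ... passed on to [run_ga()].
#' @return a `"ca3_fitresult"`.
#' @export
mutant_stage_fit <- function(control_fit, targets_mut,
                             ga_cfg = ga_config(), space = NULL, ...) {
  base_config <- if (inherits(control_fit, "circuit_config")) control_fit
                 else control_fit$best_config
  stopifnot(inherits(base_config, "circuit_config"))
  if (is.null(space)) {
    nap <- c(olm = unname(base_config$olm["gNaP"]),
             basket = unname(base_config$basket["gNaP"]),
             pyr = unname(base_config$pyr["gNaP"]))
    cnt <- base_config$counts
    space <- parameter_space(
      name = c("olm.gNaP", "basket.gNaP", "pyr.gNaP",
               "counts.OLM", "counts.basket", "counts.pyramidal"),
      lower = c(nap * 0.25, pmax(1, cnt - 3)),
      upper = c(nap * 6, cnt + 5),
      integer = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      stage = "mutant")
  } else if (attr(space, "stage") != "mutant")
    stop("space must be a mutant-stage parameter_space")
  run_ga(space, base_config, targets_mut, ga_cfg,
         preserve = "theta_power", ...)
}
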