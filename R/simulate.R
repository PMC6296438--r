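#' Simulation scenario
#'
#' Bundles what varies between runs of the same model: time span and output
#' grid, initial-state and parameter overrides, and timed events such as
#' inducer addition (modelled as an instantaneous set/add on one species).
#'
#' @param t_end End time (min); > 0.
#' @param times Output time grid; defaults to 501 evenly spaced points.
#' @param init Named numeric initial-value overrides.
#' @param params Named numeric parameter overrides.
#' @param events A data frame with columns `time`, `species`, `value` and
#'   optionally `method` (`"set"`, the default, or `"add"`). Event times must
#'   lie within `[0, t_end]`.
#' @return A `cw_scenario`.
#' @export
scenario <- function(t_end, times = NULL, init = numeric(), params = numeric(),
                     events = NULL) {
  stopifnot(t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 501L)
  stopifnot(all(diff(times) > 0), min(times) >= 0, max(times) <= t_end)
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    if (!"method" %in% names(events)) events$method <- "set"
    stopifnot(all(c("time", "species", "value") %in% names(events)),
              all(events$method %in% c("set", "add")))
    if (any(events$time < 0 | events$time > t_end)) {
      stop("event times must lie within [0, t_end]", call. = FALSE)
    }
    events <- events[order(events$time), , drop = FALSE]
  }
  structure(list(t_end = t_end, times = times, init = init, params = params,
                 events = events),
            class = "cw_scenario")
}

model_state <- function(model, sc) {
  x0 <- stats::setNames(model$species$initial, model$species$name)
  for (nm in names(sc$init)) {
    if (!nm %in% names(x0)) {
      stop("initial override for unknown species '", nm, "'", call. = FALSE)
    }
    x0[[nm]] <- sc$init[[nm]]
  }
  pars <- model$parameters
  for (nm in names(sc$params)) pars[[nm]] <- sc$params[[nm]]
  list(x0 = x0, pars = pars)
}

compile_rates <- function(model) {
  lapply(model$reactions$rate_law, function(law) parse(text = law)[[1]])
}

as_trajectory <- function(times, values, model, sc, meta = list()) {
  out <- tibble::as_tibble(as.data.frame(values))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  for (nm in names(model$observables)) {
    e <- parse(text = model$observables[[nm]])[[1]]
    env <- c(as.list(out), as.list(model$parameters))
    out[[nm]] <- eval(e, envir = env)
  }
  attr(out, "species") <- model$species$name
  attr(out, "metadata") <- meta
  class(out) <- unique(c("cw_trajectory", class(out)))
  out
}

#' Deterministic ODE simulation of a reaction model
#'
#' Integrates `dx/dt = S v(x)` with a stiff-capable solver
#' ([deSolve::lsoda()]); scenario events are applied exactly at their times.
#' Observables registered on the model are evaluated on the solution and
#' appended as columns.
#'
#' @param model A `cw_reaction_model`.
#' @param sc A [scenario()].
#' @param rtol,atol Solver tolerances.
#' @return A `cw_trajectory` tibble (`time` plus one column per species and
#'   observable).
#' @export
simulate_ode <- function(model, sc, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "cw_reaction_model"), inherits(sc, "cw_scenario"))
  st <- model_state(model, sc)
  S <- stoichiometry(model)
  storage.mode(S) <- "double"
  exprs <- compile_rates(model)
  rate_vec <- as.call(c(quote(c), exprs))
  env <- new.env(parent = baseenv())
  for (nm in names(st$pars)) assign(nm, st$pars[[nm]], envir = env)
  sp_names <- names(st$x0)
  nsp <- length(st$x0)
  deriv <- function(t, y, p) {
    for (i in seq_len(nsp)) env[[sp_names[[i]]]] <- y[[i]]
    v <- eval(rate_vec, envir = env)
    list(as.vector(S %*% v))
  }
  times <- sc$times
  ev <- NULL
  if (!is.null(sc$events) && nrow(sc$events) > 0) {
    bad <- setdiff(sc$events$species, names(st$x0))
    if (length(bad) > 0) {
      stop("event on unknown species: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    ev <- list(data = data.frame(
      var = sc$events$species, time = sc$events$time,
      value = sc$events$value,
      method = ifelse(sc$events$method == "set", "rep", "add")))
    times <- sort(unique(c(times, sc$events$time)))
  }
  sol <- deSolve::lsoda(y = st$x0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol, events = ev, maxsteps = 50000)
  if (attr(sol, "istate")[[1]] < 0) {
    stop("ODE integration failed (istate = ", attr(sol, "istate")[[1]], ")",
         call. = FALSE)
  }
  keep <- sol[, 1] %in% sc$times
  model2 <- model
  model2$parameters <- st$pars
  as_trajectory(sol[keep, 1], sol[keep, -1, drop = FALSE], model2, sc,
                meta = list(engine = "ode"))
}

#' Stochastic simulation (Gillespie direct method)
#'
#' Exact stochastic simulation of a mass-action reaction model (or a rule
#' model, which is grounded to reactions first) in count units. Reproducible
#' given a seed; the caller's RNG state is restored afterwards.
#'
#' @param model A `cw_reaction_model` whose reactions are all mass-action, or
#'   a `cw_rule_model`.
#' @param sc A [scenario()]; initial counts must be non-negative integers.
#' @param seed Integer RNG seed.
#' @return A `cw_trajectory` sampled on the scenario's output grid
#'   (piecewise-constant interpolation of the jump process).
#' @export
simulate_ssa <- function(model, sc, seed = 1L) {
  if (inherits(model, "cw_rule_model")) model <- rule_model_to_reactions(model)
  stopifnot(inherits(model, "cw_reaction_model"), inherits(sc, "cw_scenario"))
  if (!all(model$reactions$mass_action)) {
    stop("stochastic simulation requires mass-action reactions", call. = FALSE)
  }
  st <- model_state(model, sc)
  if (any(st$x0 < 0) || any(st$x0 != round(st$x0))) {
    stop("initial counts must be non-negative integers", call. = FALSE)
  }
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  S <- stoichiometry(model)
  nrx <- ncol(S)
  re_idx <- lapply(model$reactions$reactants, function(re) {
    match(names(re), model$species$name)
  })
  re_mult <- lapply(model$reactions$reactants, function(re) as.numeric(unlist(re)))
  k <- vapply(model$reactions$parameter, function(p) model$parameters[[p]],
              numeric(1))
  for (nm in names(st$pars)) {
    hit <- model$reactions$parameter == nm
    if (any(hit)) k[hit] <- st$pars[[nm]]
  }
  x <- as.numeric(st$x0)
  nsp <- length(x)
  grid <- sc$times
  out <- matrix(NA_real_, nrow = length(grid), ncol = nsp,
                dimnames = list(NULL, names(st$x0)))
  ev <- sc$events
  ev_times <- if (!is.null(ev)) ev$time else numeric()
  propensity <- function(x) {
    a <- k
    for (j in seq_len(nrx)) {
      idx <- re_idx[[j]]
      if (length(idx) == 0) next
      mult <- re_mult[[j]]
      for (q in seq_along(idx)) {
        n <- x[[idx[[q]]]]
        m <- mult[[q]]
        comb <- 1
        for (r in 0:(m - 1)) comb <- comb * (n - r)
        a[[j]] <- a[[j]] * comb / factorial(m)
      }
    }
    pmax(a, 0)
  }
  if (!is.null(ev)) {
    for (h in which(ev$time == 0)) {
      i <- match(ev$species[[h]], names(st$x0))
      x[[i]] <- if (ev$method[[h]] == "set") ev$value[[h]] else
        x[[i]] + ev$value[[h]]
    }
  }
  t_now <- 0
  gi <- 1L
  segments <- c(ev_times[ev_times > 0], sc$t_end)
  for (si in seq_along(segments)) {
    t_stop <- segments[[si]]
    repeat {
      a <- propensity(x)
      a0 <- sum(a)
      t_next <- if (a0 > 0) t_now + stats::rexp(1, a0) else Inf
      if (t_next > t_stop) {
        while (gi <= length(grid) && grid[[gi]] <= t_stop) {
          out[gi, ] <- x
          gi <- gi + 1L
        }
        t_now <- t_stop
        break
      }
      while (gi <= length(grid) && grid[[gi]] < t_next) {
        out[gi, ] <- x
        gi <- gi + 1L
      }
      t_now <- t_next
      j <- sample.int(nrx, 1L, prob = a)
      x <- x + S[, j]
    }
    if (!is.null(ev)) {
      hits <- which(abs(ev$time - t_stop) < 1e-12)
      for (h in hits) {
        i <- match(ev$species[[h]], names(st$x0))
        x[[i]] <- if (ev$method[[h]] == "set") ev$value[[h]] else
          x[[i]] + ev$value[[h]]
      }
    }
  }
  while (gi <= length(grid)) {
    out[gi, ] <- x
    gi <- gi + 1L
  }
  model2 <- model
  as_trajectory(grid, out, model2, sc,
                meta = list(engine = "ssa", seed = seed))
}

peak_prominences <- function(x) {
  n <- length(x)
  is_max <- which(diff(sign(diff(x))) < 0) + 1L
  prom <- vapply(is_max, function(i) {
    left <- x[seq_len(i - 1)]
    right <- x[(i + 1):n]
    higher_l <- which(left >= x[[i]])
    lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1):i])
    higher_r <- which(right >= x[[i]])
    rmax <- if (length(higher_r)) i + min(higher_r) else n
    rmin <- min(x[i:rmax])
    x[[i]] - max(lmin, rmin)
  }, numeric(1))
  list(index = is_max, prominence = prom)
}

#' Oscillation detector
#'
#' Classifies a trajectory as oscillating when, after discarding an initial
#' transient, it shows at least `min_peaks` maxima whose prominence exceeds
#' `prominence_frac` of the signal range and whose inter-peak intervals have
#' a coefficient of variation below `cv_max`. The thresholds are detector
#' policy, all configurable.
#'
#' @param traj A `cw_trajectory`.
#' @param species Column to analyse.
#' @param transient_frac Fraction of the record discarded as transient.
#' @param min_peaks Minimum number of qualifying peaks.
#' @param prominence_frac Minimum peak prominence, as a fraction of the
#'   post-transient signal range.
#' @param cv_max Maximum coefficient of variation of inter-peak intervals.
#' @return A list: `oscillating` (logical), `period` (mean inter-peak
#'   interval, `NA` when fewer than two peaks), `amplitude` (mean peak
#'   prominence), `n_peaks`.
#' @export
detect_oscillation <- function(traj, species, transient_frac = 0.2,
                               min_peaks = 5L, prominence_frac = 0.1,
                               cv_max = 0.2) {
  stopifnot(species %in% names(traj))
  n <- nrow(traj)
  keep <- seq_len(n) > floor(n * transient_frac)
  if (sum(keep) < 100) {
    stop("trajectory too short: need at least 100 time points after the ",
         "transient", call. = FALSE)
  }
  x <- traj[[species]][keep]
  t <- traj$time[keep]
  rng <- diff(range(x))
  if (rng == 0) {
    return(list(oscillating = FALSE, period = NA_real_, amplitude = 0,
                n_peaks = 0L))
  }
  pk <- peak_prominences(x)
  ok <- pk$prominence > prominence_frac * rng
  idx <- pk$index[ok]
  n_peaks <- length(idx)
  period <- NA_real_
  cv <- NA_real_
  if (n_peaks >= 2) {
    gaps <- diff(t[idx])
    period <- mean(gaps)
    cv <- stats::sd(gaps) / period
  }
  oscillating <- n_peaks >= min_peaks && !is.na(cv) && cv < cv_max
  list(oscillating = oscillating, period = period,
       amplitude = if (n_peaks > 0) mean(pk$prominence[ok]) else 0,
       n_peaks = n_peaks)
}

#' Restrict a trajectory to a time window
#'
#' @param traj A `cw_trajectory`.
#' @param from,to Window bounds (inclusive).
#' @return The windowed trajectory.
#' @export
window_trajectory <- function(traj, from, to) {
  out <- traj[traj$time >= from & traj$time <= to, , drop = FALSE]
  class(out) <- unique(c("cw_trajectory", class(out)))
  out
}

#' Run a switchable-oscillator scenario
#'
#' Simulates a protease-coupled switch/oscillator model through an inducer
#' event and reports the oscillation classification of the oscillator
#' readout in the windows before and after induction, together with the
#' switch-state levels of the tagged switch protein. The switchable-oscillator
#' criterion is: not oscillating before the event, oscillating after it.
#'
#' @param coupled A model from [apply_protease_coupling()].
#' @param sc A [scenario()] containing at least one event (the inducer
#'   addition).
#' @param readout Species column used for oscillation detection; defaults to
#'   the oscillator GFP (`osc_GFP`).
#' @param switch_species Tagged switch species; defaults to the coupled
#'   model's `tag_switch` attribute.
#' @param ... Passed to [detect_oscillation()].
#' @return A list of class `cw_switch_report`: `pre`, `post` (detector
#'   results), `switch_level_pre`, `switch_level_post`, `switchable`
#'   (logical), `event_time`.
#' @export
run_switchable_scenario <- function(coupled, sc, readout = "osc_GFP",
                                    switch_species = attr(coupled, "tag_switch"),
                                    ...) {
  if (is.null(sc$events) || nrow(sc$events) == 0) {
    stop("scenario error: a switchable-oscillator scenario requires an ",
         "inducer event", call. = FALSE)
  }
  t_event <- min(sc$events$time)
  traj <- simulate_ode(coupled, sc)
  pre <- detect_oscillation(window_trajectory(traj, 0, t_event), readout, ...)
  post <- detect_oscillation(window_trajectory(traj, t_event, sc$t_end),
                             readout, ...)
  pre_win <- window_trajectory(traj, 0, t_event)
  post_win <- window_trajectory(traj, t_event, sc$t_end)
  lvl <- function(w) {
    n <- nrow(w)
    mean(w[[switch_species]][seq(floor(n / 2), n)])
  }
  structure(
    list(pre = pre, post = post,
         switch_level_pre = lvl(pre_win), switch_level_post = lvl(post_win),
         switchable = !pre$oscillating && post$oscillating,
         event_time = t_event, trajectory = traj),
    class = "cw_switch_report"
  )
}

#' @export
print.cw_switch_report <- function(x, ...) {
  cat("<cw_switch_report> event at t=", x$event_time, " min\n",
      "  pre:  oscillating=", x$pre$oscillating, " (", x$pre$n_peaks,
      " peaks)\n",
      "  post: oscillating=", x$post$oscillating, " (", x$post$n_peaks,
      " peaks, period ", round(x$post$period %||% NA, 2), " min)\n",
      "  switch level: ", signif(x$switch_level_pre, 3), " -> ",
      signif(x$switch_level_post, 3), "\n",
      "  switchable: ", x$switchable, "\n", sep = "")
  invisible(x)
}
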