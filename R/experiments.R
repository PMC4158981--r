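#' Sweep choice predictions over expected attention times
#'
#' Recomputes choice probabilities and mean response times across a grid of
#' expected attention times (in chain steps) and a set of attention-time
#' distribution kinds, holding the attributes, discretization and attribute
#' order fixed.  This is the standard numerical experiment for studying how
#' attention-time variance shapes predictions: at each grid value every
#' requested kind is parameterized to the same mean, with the deterministic
#' kind serving as the variance-0 reference.
#'
#' @param attrs List of \code{\link{attribute_params}}.
#' @param disc A \code{\link{build_discretization}} object.
#' @param order Fixed attribute order (integer vector), one stage per
#'   entry.
#' @param grid Expected attention times (default 50 evenly spaced values
#'   from 10 to 500), interpreted per \code{grid_units}.
#' @param grid_units \code{"steps"}: grid values are expected chain steps
#'   \eqn{E(T_{at})}.  \code{"time"}: grid values are expected real
#'   attention times \eqn{\tau E(T_{at})} and are converted to steps by
#'   dividing by \code{disc$tau} (the natural axis for plotting against
#'   physical time).
#' @param kinds Distribution kinds to compare; \code{"uniform_half"} and
#'   \code{"uniform_full"} denote the uniform kind with \eqn{M = N/2} and
#'   \eqn{M = N - 1}.
#' @param horizon \code{"infinite"}: the final stage runs to absorption and
#'   only the earlier stages draw random times.  \code{"finite"}: every
#'   stage, including the last, draws from the same distribution.
#' @param Z Initial distribution over transient states.
#' @param tol Series truncation tolerance.
#'
#' @return A data frame with one row per (kind, grid value):
#'   \code{kind}, \code{expected_attention_steps}, \code{p_A}, \code{p_B},
#'   \code{p_0}, \code{ET_A}, \code{ET_B}, \code{initial_attribute}.
#'   Grid points violating the stability constraint are skipped with a
#'   warning.
#' @examples
#' disc <- build_discretization(10, tau = 1 / 16)
#' attrs <- list(attribute_params(0.2, 0.03), attribute_params(0.04, 0.003))
#' run_sweep(attrs, disc, order = c(1, 2), grid = c(100, 300),
#'           kinds = c("deterministic", "geometric"))
#' @export
run_sweep <- function(attrs, disc, order, grid = seq(10, 500, length.out = 50),
                      kinds = c("deterministic", "geometric", "uniform_half",
                                "uniform_full", "poisson", "binomial"),
                      horizon = c("infinite", "finite"),
                      grid_units = c("steps", "time"),
                      Z = initial_state(disc), tol = 1e-12) {
  horizon <- match.arg(horizon)
  grid_units <- match.arg(grid_units)
  attrs <- as_attribute_list(attrs)
  stopifnot(length(grid) > 0, all(grid > 0))
  if (grid_units == "time") grid <- grid / disc$tau
  if (any(grid < 1))
    stop("expected attention times must be at least one chain step",
         call. = FALSE)
  kinds <- match.arg(kinds, several.ok = TRUE)
  rows <- vector("list", length(kinds) * length(grid))
  i <- 0L
  for (kind in kinds) {
    for (g in grid) {
      i <- i + 1L
      dist <- sweep_dist(kind, g)
      sched <- time_order_schedule(order = order, times = dist,
                                   horizon = horizon)
      res <- tryCatch(
        solve_random(sched, attrs, disc, Z = Z, tol = tol)$aggregate,
        error = function(e) {
          warning(sprintf("skipping kind %s at mean %g: %s", kind, g,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(res)) next
      rows[[i]] <- data.frame(
        kind = kind, expected_attention_steps = g,
        p_A = res$p_A, p_B = res$p_B, p_0 = res$p_0,
        ET_A = res$ET_A, ET_B = res$ET_B,
        initial_attribute = order[1])
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Translate a sweep kind label plus target mean into a distribution.
sweep_dist <- function(kind, mean) {
  switch(kind,
    deterministic = attention_time("deterministic", mean = mean),
    geometric     = attention_time("geometric", mean = mean),
    uniform_half  = attention_time("uniform", mean = mean, spread = "half"),
    uniform_full  = attention_time("uniform", mean = mean, spread = "full"),
    poisson       = attention_time("poisson", mean = mean),
    binomial      = attention_time("binomial", mean = mean),
    stop(sprintf("unknown sweep kind '%s'", kind), call. = FALSE))
}

# ---------------------------------------------------------------------------
# Config-driven runs

parse_config_dist <- function(spec) {
  spec <- as.list(spec)
  kind <- spec$kind
  if (is.null(kind)) stop("distribution spec is missing `kind`",
                          call. = FALSE)
  if (!is.null(spec$mean)) {
    attention_time(kind, mean = spec$mean,
                   spread = if (!is.null(spec$spread)) spec$spread
                            else "half")
  } else {
    do.call(attention_time, c(list(kind = kind),
                              spec[setdiff(names(spec), "kind")]))
  }
}

parse_config_schedule <- function(cfg) {
  sc <- cfg$schedule
  if (is.null(sc)) stop("config is missing `schedule`", call. = FALSE)
  order <- if (!is.null(sc$order_fixed)) as.integer(unlist(sc$order_fixed))
           else list(init = unlist(sc$order_init),
                     D = lapply(sc$order_matrices, function(D) {
                       if (is.matrix(D)) D
                       else matrix(unlist(D), nrow = length(D),
                                   byrow = TRUE)
                     }))
  times <- sc$times
  times <- if (is.numeric(unlist(times)) &&
               !("kind" %in% names(unlist(times))) &&
               is.null(names(times))) as.integer(unlist(times))
           else if ("kind" %in% names(times)) parse_config_dist(times)
           else lapply(times, parse_config_dist)
  time_order_schedule(order = order, times = times,
                      horizon = if (is.null(sc$horizon)) "finite"
                                else sc$horizon,
                      L = sc$L)
}

parse_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("mode", "attributes", "discretization"))
    if (is.null(cfg[[fld]]))
      stop(sprintf("config is missing required field `%s`", fld),
           call. = FALSE)
  cfg
}

config_objects <- function(cfg) {
  attr_specs <- cfg$attributes
  if (is.data.frame(attr_specs))   # JSON arrays of objects simplify to this
    attr_specs <- lapply(seq_len(nrow(attr_specs)), function(i)
      as.list(attr_specs[i, ]))
  attrs <- lapply(attr_specs, function(a) {
    a <- as.list(a)
    if (is.null(a$delta)) stop("attribute entry is missing `delta`",
                               call. = FALSE)
    attribute_params(a$delta,
                     if (is.null(a$gamma)) 0 else a$gamma,
                     if (is.null(a$sigma)) 1 else a$sigma)
  })
  d <- cfg$discretization
  if (is.null(d$tau)) stop("discretization is missing `tau`", call. = FALSE)
  disc <- build_discretization(
    theta_A = if (is.null(d$theta_A)) 10 else d$theta_A,
    theta_B = if (is.null(d$theta_B)) {
      if (is.null(d$theta_A)) 10 else d$theta_A
    } else d$theta_B,
    sigma = if (is.null(d$sigma)) 1 else d$sigma,
    tau = d$tau)
  Z <- if (!is.null(cfg$start_at)) initial_state(disc, at = cfg$start_at)
       else initial_state(disc)
  list(attrs = attrs, disc = disc, Z = Z)
}

#' Run a configuration file
#'
#' Executes the mode requested by a YAML or JSON configuration and writes
#' result files to \code{outdir}.  Modes:
#' \describe{
#'   \item{single}{one \code{\link{solve_random}} (or deterministic) solve;
#'     writes \code{result.json}.}
#'   \item{sweep}{\code{\link{run_sweep}} over a grid; writes
#'     \code{sweep.csv}.}
#'   \item{simulate}{\code{\link{simulate_trials}}; writes
#'     \code{trials.csv} and \code{simulation.json}.}
#'   \item{compare}{solver and simulator on the same schedule; writes
#'     \code{compare.csv} with deviations in standard-error units.}
#' }
#' A \code{run_log.txt} with parameters and warnings and a
#' \code{metadata.json} record accompany every run.
#'
#' @param path Path to the config file (\code{.yaml}, \code{.yml} or
#'   \code{.json}).
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the config's seed.
#' @param mode Optional mode override.
#' @return Invisibly, a list of the result objects written.
#' @export
run_config <- function(path, outdir = ".", seed = NULL, mode = NULL) {
  cfg <- parse_config(path)
  if (!is.null(mode)) cfg$mode <- mode
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mode: %s", cfg$mode),
                 sprintf("seed: %d", as.integer(cfg$seed)),
                 sprintf("config: %s", normalizePath(path)))
  obj <- withCallingHandlers(
    config_objects(cfg),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  out <- list()

  if (cfg$mode == "sweep") {
    sw <- cfg$sweep
    if (is.null(sw)) stop("sweep mode needs a `sweep` block", call. = FALSE)
    grid <- if (!is.null(sw$grid)) as.numeric(unlist(sw$grid))
            else seq(10, 500, length.out = 50)
    kinds <- if (!is.null(sw$kinds)) unlist(sw$kinds)
             else c("deterministic", "geometric")
    tab <- run_sweep(obj$attrs, obj$disc,
                     order = as.integer(unlist(sw$order)),
                     grid = grid, kinds = kinds,
                     horizon = if (is.null(sw$horizon)) "infinite"
                               else sw$horizon,
                     grid_units = if (is.null(sw$grid_units)) "steps"
                                  else sw$grid_units,
                     Z = obj$Z)
    utils::write.csv(tab, file.path(outdir, "sweep.csv"),
                     row.names = FALSE)
    out$sweep <- tab
  } else {
    sched <- parse_config_schedule(cfg)
    diag <- validate_schedule(sched, length(obj$attrs))
    hard <- diag[!startsWith(diag, "warning:")]
    if (length(hard)) stop(paste(hard, collapse = "; "), call. = FALSE)
    log_lines <- c(log_lines, diag)

    if (cfg$mode == "single") {
      res <- solve_random(sched, obj$attrs, obj$disc, Z = obj$Z)
      rec <- list(per_initial = res$per_initial,
                  aggregate = as.data.frame(res$aggregate),
                  metadata = config_metadata(cfg, obj))
      jsonlite::write_json(rec, file.path(outdir, "result.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out$result <- res
    } else if (cfg$mode == "simulate") {
      n <- if (is.null(cfg$n_trials)) 10000L else as.integer(cfg$n_trials)
      sim <- simulate_trials(sched, obj$attrs, obj$disc, Z = obj$Z,
                             n_trials = n, seed = as.integer(cfg$seed))
      export_trials_csv(sim, file.path(outdir, "trials.csv"))
      jsonlite::write_json(
        list(empirical = sim$empirical, counts = as.list(sim$counts),
             metadata = config_metadata(cfg, obj)),
        file.path(outdir, "simulation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out$simulation <- sim
    } else if (cfg$mode == "compare") {
      n <- if (is.null(cfg$n_trials)) 10000L else as.integer(cfg$n_trials)
      sol <- solve_random(sched, obj$attrs, obj$disc, Z = obj$Z)$aggregate
      sim <- simulate_trials(sched, obj$attrs, obj$disc, Z = obj$Z,
                             n_trials = n, seed = as.integer(cfg$seed))
      cmp <- compare_solver_simulator(sol, sim)
      utils::write.csv(cmp, file.path(outdir, "compare.csv"),
                       row.names = FALSE)
      out$compare <- cmp
    } else {
      stop(sprintf("unknown mode '%s' (use single, sweep, simulate, compare)",
                   cfg$mode), call. = FALSE)
    }
  }
  jsonlite::write_json(config_metadata(cfg, obj),
                       file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(out)
}

config_metadata <- function(cfg, obj) {
  list(mode = cfg$mode, seed = cfg$seed,
       attributes = lapply(obj$attrs, function(a)
         list(delta = a$delta, gamma = a$gamma, sigma = a$sigma)),
       discretization = list(
         m = obj$disc$m, m_A = obj$disc$m_A, m_B = obj$disc$m_B,
         tau = obj$disc$tau, delta_x = obj$disc$delta_x,
         effective_theta_A = obj$disc$m_A * obj$disc$delta_x,
         effective_theta_B = -obj$disc$m_B * obj$disc$delta_x),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Tabulate solver-vs-simulator deviations in standard-error units
#'
#' @param solver_result A \code{maas_result} (e.g. the aggregate from
#'   \code{\link{solve_random}}).
#' @param sim A \code{\link{simulate_trials}} object for the same schedule.
#' @return A data frame with columns \code{quantity}, \code{solver},
#'   \code{simulator}, \code{se}, \code{deviation_se}.
#' @export
compare_solver_simulator <- function(solver_result, sim) {
  stopifnot(inherits(solver_result, "maas_result"),
            inherits(sim, "maas_sim"))
  e <- sim$empirical
  q <- c("p_A", "p_B", "p_0", "ET_A", "ET_B")
  sol <- unlist(solver_result[q])
  emp <- unlist(e[q])
  se <- unlist(e[paste0("se_", q)])
  data.frame(quantity = q, solver = unname(sol), simulator = unname(emp),
             se = unname(se),
             deviation_se = unname((emp - sol) / ifelse(se > 0, se, NA)))
}
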