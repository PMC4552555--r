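# Model/dataset file formats and the command-line style driver tying the
# pipeline together. All outputs are plain text (JSON/CSV) with 17
# significant digits, so runs diff cleanly and reproduce bit-stably.

.MODEL_SCHEMA <- "smolcrn-model-v1"

#' Read / write the declarative model file (JSON)
#'
#' The model document carries `species`, `x0`, `time_grid`, `observables`
#' and `reactions` (each with `educts`, `products`, a `param` block
#' `{name, nominal, lower, upper, space}` and optional `input`
#' coefficients). Write-then-parse is stable modulo key order. Networks
#' with time-varying inputs need `input_fn` supplied at parse time (the
#' signal itself is not serializable).
#'
#' @param path File path.
#' @param input_fn Optional input signal for networks declaring inputs.
#' @return `parse_model_file()`: a `reaction_network`.
#' @export
parse_model_file <- function(path, input_fn = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, .MODEL_SCHEMA)) {
    stop("model schema mismatch: expected '", .MODEL_SCHEMA, "'", call. = FALSE)
  }
  need <- c("species", "x0", "time_grid", "reactions")
  for (f in need) {
    if (is.null(obj[[f]])) stop("model file missing field '", f, "'", call. = FALSE)
  }
  species <- unlist(obj$species)
  rxns <- lapply(seq_along(obj$reactions), function(j) {
    r <- obj$reactions[[j]]
    if (is.null(r$param)) stop("reaction ", j, ": missing 'param' block", call. = FALSE)
    pb <- r$param
    for (f in c("name", "nominal", "lower", "upper")) {
      if (is.null(pb[[f]])) {
        stop("reaction ", j, ": param block missing field '", f, "'", call. = FALSE)
      }
    }
    reaction(
      educts = as.character(unlist(r$educts)),
      products = as.character(unlist(r$products)),
      rate = rate_param(pb$name, pb$nominal, pb$lower, pb$upper,
        space = if (is.null(pb$space)) "linear" else pb$space
      ),
      input = if (is.null(r$input)) NULL else unlist(r$input)
    )
  })
  x0 <- unlist(obj$x0)[species]
  observables <- if (is.null(obj$observables)) NULL else unlist(obj$observables)
  reaction_network(rxns,
    x0 = x0, time_grid = unlist(obj$time_grid),
    observables = observables, input_fn = input_fn
  )
}

#' @rdname parse_model_file
#' @param network A `reaction_network`.
#' @return `write_model_file()`: the path, invisibly.
#' @export
write_model_file <- function(network, path) {
  rxns <- lapply(seq_along(network$reactions), function(j) {
    rx <- network$reactions[[j]]
    k <- network$param_index[j]
    out <- list(
      educts = as.list(rx$educts),
      products = as.list(rx$products),
      param = list(
        name = network$params$name[k],
        nominal = network$params$nominal[k],
        lower = network$params$lower[k],
        upper = network$params$upper[k],
        space = network$params$space[k]
      )
    )
    if (!is.null(rx$input)) out$input <- as.list(rx$input)
    out
  })
  obj <- list(
    schema = .MODEL_SCHEMA,
    species = as.list(network$species),
    x0 = as.list(stats::setNames(network$x0, network$species)),
    time_grid = network$time_grid,
    observables = as.list(network$observables),
    reactions = rxns
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a dataset file (CSV: time, observable, value, variance)
#'
#' @param path File path.
#' @return `read_dataset_csv()`: a `crn_dataset` (diagonal noise).
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "observable", "value", "variance")
  if (!all(need %in% names(d))) {
    stop("dataset CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  times <- sort(unique(d$time))
  obs <- unique(d$observable)
  structure(
    list(
      data = tibble::as_tibble(d[need]), times = times, observables = obs,
      p_true_tilde = NULL, noise_sd = sqrt(unique(d$variance)), seed = NA_integer_
    ),
    class = "crn_dataset"
  )
}

#' @rdname read_dataset_csv
#' @param dataset A `crn_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  .write_csv17(dataset$data, path)
  invisible(path)
}

# CSV writer with bit-stable 17-significant-digit numeric formatting;
# character columns (e.g. comma-separated multi-indices) are quoted
.write_csv17 <- function(d, path) {
  d <- as.data.frame(d)
  char_cols <- integer(0)
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]]) && !is.integer(d[[j]])) {
      d[[j]] <- sprintf("%.17g", d[[j]])
    } else if (is.character(d[[j]]) || is.factor(d[[j]])) {
      char_cols <- c(char_cols, j)
    }
  }
  utils::write.csv(d, path, row.names = FALSE, quote = char_cols)
}

#' Write a convergence record as CSV
#'
#' @param record Convergence record tibble (or a `sparse_approx`).
#' @param path File path.
#' @export
write_convergence_csv <- function(record, path) {
  if (inherits(record, "sparse_approx")) record <- record$record
  .write_csv17(record, path)
  invisible(path)
}

#' Pipeline driver (one mode per call)
#'
#' Runs one analysis mode on a model file (or `reaction_network`) and
#' writes its artifacts — convergence CSV, result JSON, surrogate file,
#' chain CSV — into an output directory, plus a human-readable log with
#' one line per adaptation iteration. This is the engine behind the
#' `inst/cli/smolcrn` command-line script.
#'
#' @param config A list (or `run_config()`) with fields: `mode` (one of
#'   `"simulate"`, `"surrogate"`, `"evidence"`, `"posterior"`, `"mcmc"`,
#'   `"sensitivity"`, `"sloppiness"`, `"extend-box"`), `model` (path or
#'   `reaction_network`), `output` directory, and optionally `tol`,
#'   `budget`, `seed`, `dataset` (path or `crn_dataset`), `region`
#'   (overrides ranges to `+/- region * p0`), `n_samples`, `rtol`, `atol`,
#'   `allow_partial`.
#' @return Invisibly, a list of the computed results and written paths;
#'   errors (or, unless `allow_partial`, non-convergence) raise
#'   conditions.
#' @export
run_command <- function(config) {
  cfg <- do.call(run_config, config)
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  net <- if (inherits(cfg$model, "reaction_network")) cfg$model else parse_model_file(cfg$model)
  if (!is.null(cfg$region)) net <- .apply_region(net, cfg$region)
  logf <- file.path(cfg$output, "run.log")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  logline <- function(...) writeLines(paste0(...), logcon)
  logline("mode: ", cfg$mode, " | tol: ", cfg$tol, " | budget: ", cfg$budget, " | seed: ", cfg$seed)

  paths <- list(log = logf)
  res <- list()

  log_record <- function(fit) {
    rec <- fit$record
    for (i in seq_len(nrow(rec))) {
      logline(sprintf(
        "iter %d | selected (%s) | M %d | indicator %.6g",
        rec$iteration[i], rec$selected_index[i], rec$n_evaluations[i], rec$indicator[i]
      ))
    }
    logline(
      "accepted grid points: ", fit$n_accepted_points,
      " | iterations: ", fit$n_iterations, " | converged: ", fit$converged
    )
    if (!fit$converged && !cfg$allow_partial) {
      stop("adaptation did not converge within budget ", cfg$budget,
        " (rerun with allow_partial = TRUE to keep partial artifacts)",
        call. = FALSE
      )
    }
  }

  if (cfg$mode == "simulate") {
    traj <- solve_trajectory(net, rtol = cfg$rtol, atol = cfg$atol)
    paths$trajectory <- file.path(cfg$output, "trajectory.csv")
    .write_csv17(traj, paths$trajectory)
    res$trajectory <- traj
  } else if (cfg$mode == "surrogate") {
    ev <- network_evaluator(net, rtol = cfg$rtol, atol = cfg$atol)
    fit <- adapt_smolyak(ev,
      n_dims = length(active_parameters(net)),
      tol = cfg$tol, budget = cfg$budget
    )
    log_record(fit)
    paths$surrogate <- file.path(cfg$output, "surrogate.smolyak.json")
    save_surrogate(fit, paths$surrogate)
    paths$convergence <- file.path(cfg$output, "convergence.csv")
    write_convergence_csv(fit, paths$convergence)
    res$approx <- fit
  } else if (cfg$mode %in% c("evidence", "posterior", "mcmc")) {
    if (is.null(cfg$dataset)) stop("mode '", cfg$mode, "' needs a dataset", call. = FALSE)
    ds <- if (inherits(cfg$dataset, "crn_dataset")) cfg$dataset else read_dataset_csv(cfg$dataset)
    ll <- likelihood_function(ds, dataset_forward(net, ds, rtol = cfg$rtol, atol = cfg$atol))
    nd <- length(active_parameters(net))
    if (cfg$mode == "evidence") {
      evd <- evidence(ll, nd, tol = cfg$tol, budget = cfg$budget)
      log_record(evd$approx)
      paths$convergence <- file.path(cfg$output, "convergence.csv")
      write_convergence_csv(evd$record, paths$convergence)
      paths$result <- file.path(cfg$output, "result.json")
      jsonlite::write_json(
        list(
          evidence = evd$evidence, log_evidence = evd$log_evidence,
          n_evaluations = evd$n_evaluations, converged = evd$converged
        ),
        paths$result,
        auto_unbox = TRUE, digits = NA
      )
      res$evidence <- evd
    } else if (cfg$mode == "posterior") {
      pe <- posterior_expectation(function(p) p, ll, nd, tol = cfg$tol, budget = cfg$budget)
      paths$convergence <- file.path(cfg$output, "convergence.csv")
      write_convergence_csv(pe$record, paths$convergence)
      paths$result <- file.path(cfg$output, "result.json")
      jsonlite::write_json(
        list(
          posterior_mean_p_tilde = pe$value, evidence = pe$evidence,
          n_evaluations = pe$n_evaluations, converged = pe$converged
        ),
        paths$result,
        auto_unbox = TRUE, digits = NA
      )
      res$posterior <- pe
    } else {
      chain <- mh_mcmc(ll, nd, n_samples = cfg$n_samples, seed = cfg$seed)
      logline(
        "mcmc samples: ", nrow(chain$samples),
        " | acceptance: ", signif(chain$acceptance_rate, 4)
      )
      paths$chain <- file.path(cfg$output, "chain.csv")
      .write_csv17(tidy(chain), paths$chain)
      res$chain <- chain
    }
  } else if (cfg$mode == "sensitivity") {
    sens <- first_order_sensitivities(net, rtol = cfg$rtol, atol = cfg$atol)
    paths$result <- file.path(cfg$output, "sensitivity.json")
    jsonlite::write_json(
      list(profile = as.list(sens$profile)),
      paths$result,
      auto_unbox = TRUE, digits = NA
    )
    res$sensitivities <- sens
  } else if (cfg$mode == "sloppiness") {
    ev <- network_evaluator(net, rtol = cfg$rtol, atol = cfg$atol)
    fit <- adapt_smolyak(ev,
      n_dims = length(active_parameters(net)),
      tol = cfg$tol, budget = cfg$budget
    )
    log_record(fit)
    slop <- chi2_hessian_eigenvalues(net, surrogate = fit)
    act <- index_activation_profile(fit)
    corr <- activation_eigenvalue_correlation(slop, act, seed = cfg$seed)
    paths$result <- file.path(cfg$output, "sloppiness.json")
    jsonlite::write_json(
      list(
        eigenvalues = slop$eigenvalues,
        activation_scores = act$score,
        rank_correlation = corr$correlation,
        p_value = corr$p_value
      ),
      paths$result,
      auto_unbox = TRUE, digits = NA
    )
    res$sloppiness <- slop
    res$correlation <- corr
  } else if (cfg$mode == "extend-box") {
    ev <- network_evaluator(net, rtol = cfg$rtol, atol = cfg$atol)
    fit <- adapt_smolyak(ev,
      n_dims = length(active_parameters(net)),
      tol = cfg$tol, budget = cfg$budget
    )
    log_record(fit)
    net2 <- extend_parameter_box(fit, net, growth_factor = cfg$growth_factor)
    paths$model <- file.path(cfg$output, "extended-model.json")
    write_model_file(net2, paths$model)
    res$network <- net2
  }
  invisible(c(res, list(paths = paths, config = cfg)))
}

#' @rdname run_command
#' @param mode,model,output,tol,budget,seed,dataset,region,n_samples,rtol,atol,allow_partial,growth_factor
#'   See `run_command()`.
#' @export
run_config <- function(mode, model, output = tempfile("smolcrn-run-"),
                       tol = 1e-6, budget = 1e5, seed = 1L, dataset = NULL,
                       region = NULL, n_samples = 10000L,
                       rtol = 1e-8, atol = 1e-10,
                       allow_partial = FALSE, growth_factor = 2) {
  mode <- match.arg(mode, c(
    "simulate", "surrogate", "evidence", "posterior",
    "mcmc", "sensitivity", "sloppiness", "extend-box"
  ))
  stopifnot(tol > 0, budget >= 1)
  list(
    mode = mode, model = model, output = output, tol = tol, budget = budget,
    seed = seed, dataset = dataset, region = region, n_samples = n_samples,
    rtol = rtol, atol = atol, allow_partial = allow_partial,
    growth_factor = growth_factor
  )
}

# override all active parameter ranges to +/- region * p0 about the nominal
.apply_region <- function(network, region) {
  params <- network$params
  act <- active_parameters(network)
  for (k in act) {
    p0 <- params$nominal[k]
    params$lower[k] <- max(0, p0 * (1 - region))
    params$upper[k] <- p0 * (1 + region)
  }
  network$params <- params
  network
}
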