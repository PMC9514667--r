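#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON configuration describing a model and an
#' experiment, resolves presets, validates the schema (unknown keys are
#' rejected) and returns an `experiment_config`. The model block accepts
#' preset names (`flavin_3N`, `flavin_5N`, `ascorbyl_H4`, `superoxide`)
#' or inline radical definitions; rates may be given in aggregate
#' (`k_X`, `k_Sigma`) or component (`k_X`, `k_F`, `k_E`, `k_Ep`, `k_Xp`)
#' form, and giving both is validated for consistency.
#'
#' Example (YAML):
#' ```yaml
#' model:
#'   radical1: flavin_3N
#'   radical1_mobility: free
#'   radical3: ascorbyl_H4
#'   rates: {k_X: 1.0, k_Sigma: 0.1}
#'   phi: 0.0
#' experiment:
#'   type: sweep
#'   B_values: [0.29, 1, 10, 55.26]
#'   reference: 55.26
#' quadrature: {n_directions: 72}
#' ```
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return object of class `experiment_config` with elements `model` (a
#'   [reduced_pair_model()]), `experiment` (validated parameter list) and
#'   `quadrature`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

#' @rdname load_config
#' @param config a configuration given directly as a named list.
#' @export
validate_config <- function(config) {
  allowed_top <- c("model", "experiment", "quadrature", "output",
                   "log_level")
  check_keys(config, allowed_top, "top level")
  if (is.null(config$model)) stop("config requires a 'model' block",
                                  call. = FALSE)
  mb <- config$model
  check_keys(mb, c("radical1", "radical1_mobility", "radical3", "rates",
                   "phi", "relaxation"), "model")
  rates_in <- mb$rates
  check_keys(rates_in, c("k_X", "k_Sigma", "k_F", "k_E", "k_Ep", "k_Xp"),
             "model$rates")
  if (is.null(rates_in$k_X)) stop("rates must include k_X", call. = FALSE)
  rates <- rate_set(k_X = rates_in$k_X, k_Sigma = rates_in$k_Sigma,
                    k_F = rates_in$k_F, k_E = rates_in$k_E,
                    k_Ep = rates_in$k_Ep, k_Xp = rates_in$k_Xp,
                    phi = mb$phi %||% 0)
  relax <- mb$relaxation %||% list()
  check_keys(relax, c("gamma1", "gamma3"), "model$relaxation")
  model <- reduced_pair_model(
    radical_from_spec(mb$radical1 %||% "flavin_3N",
                      mobility = mb$radical1_mobility %||% "free"),
    radical_from_spec(mb$radical3 %||% "ascorbyl_H4"),
    rates,
    gamma1 = relax$gamma1 %||% 0, gamma3 = relax$gamma3 %||% 0
  )
  exp_block <- config$experiment %||% list(type = "mfe")
  type <- match.arg(exp_block$type %||% "mfe",
                    c("sweep", "map", "mfe", "validate"))
  allowed_exp <- switch(
    type,
    sweep = c("type", "B_values", "reference"),
    map = c("type", "kX_from", "kX_to", "kSigma_from", "kSigma_to",
            "points_per_decade", "B", "B_ref"),
    mfe = c("type", "B", "B_ref"),
    validate = c("type", "gamma2_ladder", "B")
  )
  check_keys(exp_block, allowed_exp, "experiment")
  quad <- config$quadrature %||% list()
  check_keys(quad, "n_directions", "quadrature")
  structure(
    list(model = model, experiment = c(list(type = type),
                                       exp_block[names(exp_block) != "type"]),
         quadrature = list(n_directions = quad$n_directions %||% 72),
         output = config$output %||% list(),
         log_level = config$log_level %||% "info"),
    class = "experiment_config"
  )
}

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible(NULL))
  bad <- setdiff(names(block), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Run the experiment described by a configuration
#'
#' Dispatches to [field_sweep()], [rate_map()], [mfe_ratio()] or
#' [reduction_convergence()] according to the config's experiment type.
#' Deterministic: identical configurations produce identical results.
#'
#' @param config an `experiment_config` from [load_config()], or a path.
#' @return the corresponding result object (tibble).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "experiment_config"))
  ex <- config$experiment
  nd <- config$quadrature$n_directions
  model <- config$model
  # [[ ]] access throughout: $ would partial-match (e.g. B -> B_values)
  num <- function(key, default) {
    v <- ex[[key, exact = TRUE]]
    if (is.null(v)) default else as.numeric(unlist(v))
  }
  switch(
    ex$type,
    sweep = field_sweep(model, num("B_values", c(HMF_uT, GMF_uT)),
                        reference = num("reference", GMF_uT),
                        n_directions = nd),
    map = rate_map(
      model,
      kX_grid = log_grid(num("kX_from", 1e-2), num("kX_to", 1e3),
                         num("points_per_decade", 10)),
      kSigma_grid = log_grid(num("kSigma_from", 1e-2), num("kSigma_to", 1e2),
                             num("points_per_decade", 10)),
      B = num("B", HMF_uT), B_ref = num("B_ref", GMF_uT),
      n_directions = nd
    ),
    mfe = {
      chi <- mfe_ratio(model, num("B", HMF_uT), num("B_ref", GMF_uT),
                       n_directions = nd)
      tibble::tibble(B_uT = as_field_condition(num("B", HMF_uT))$magnitude,
                     B_ref_uT = as_field_condition(num("B_ref", GMF_uT))$magnitude,
                     chi = as.numeric(chi),
                     effect_pct = attr(chi, "effect_pct"))
    },
    validate = {
      sys <- triad_system("superoxide", "superoxide", "superoxide",
                          k_F = 1, k_X = 1)
      reduction_convergence(sys,
                            field_vector(num("B", GMF_uT)),
                            gamma2_ladder = num("gamma2_ladder",
                                                c(10, 100, 1000)))
    }
  )
}

#' Write results with a provenance header
#'
#' CSV output carries the provenance (package version, field conditions,
#' orientation policy) as `#`-prefixed comment lines followed by the long
#' format table; JSON output nests the same header beside the data.
#'
#' @param results a tibble (e.g. from [field_sweep()] or [rate_map()]).
#' @param path output file path.
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (nrow(results) == 0) stop("results are empty", call. = FALSE)
  header <- list(
    package = "triadspin",
    version = as.character(utils::packageVersion("triadspin")),
    class = class(results)[1],
    B_uT = attr(results, "B_uT"),
    B_ref_uT = attr(results, "B_ref_uT") %||% attr(results, "reference_uT"),
    orientation_policy = attr(results, "orientation_policy")
  )
  header <- header[!vapply(header, is.null, logical(1))]
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(header)) {
      writeLines(sprintf("# %s: %s", nm, header[[nm]]), con)
    }
    utils::write.csv(as.data.frame(results), con, row.names = FALSE)
  } else {
    jsonlite::write_json(list(provenance = header, data = results), path,
                         digits = NA, auto_unbox = TRUE, dataframe = "rows")
  }
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path file path.
#' @return tibble (provenance in attribute `provenance`).
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::as_tibble(obj$data)
    attr(out, "provenance") <- obj$provenance
    return(out)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  out <- tibble::as_tibble(utils::read.csv(text = lines[setdiff(
    seq_along(lines), hdr)]))
  attr(out, "provenance") <- sub("^# ", "", lines[hdr])
  out
}

#' Generate toy fixture systems with reference yields
#'
#' Writes a JSON fixture set of desk-scale systems with independently
#' computed reference outputs: the zero-nucleus pair (exact closed form
#' (1/4) k_X / (k_X + k_Sigma)), a one-proton pair solved by the ODE
#' oracle, and an electrons-only triad solved in the full three-radical
#' space. Deterministic (no randomness), so regeneration reproduces the
#' stored values.
#'
#' @param outdir output directory (created if missing).
#' @return path of the written JSON file, invisibly.
#' @export
generate_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pair0 <- reduced_pair_model("superoxide", "superoxide",
                              rate_set(k_X = 1, k_Sigma = 1))
  one_proton <- reduced_pair_model(
    radical("toy1", list(nucleus("H", 2L, hyperfine_tensor(10)))),
    radical_preset("superoxide"),
    rate_set(k_X = 1, k_Sigma = 0.1)
  )
  triad0 <- triad_system("superoxide", "superoxide", "superoxide",
                         k_F = 1, k_X = 1, gamma2 = 1000)
  fixtures <- list(
    no_nucleus_pair = list(
      description = "zero-hyperfine pair, closed form (1/4) kX/(kX+kSigma)",
      k_X = 1, k_Sigma = 1, B_uT = 50,
      method = "closed_form", tolerance = 1e-12,
      phi_X = 0.25 * 1 / (1 + 1)
    ),
    one_proton_pair = list(
      description = "one spin-1/2 nucleus, a_iso = 10 MHz, B = 0",
      a_iso_MHz = 10, k_X = 1, k_Sigma = 0.1, B_uT = 0,
      method = "ode_oracle", tolerance = 1e-6,
      phi_X = unname(ode_yield(one_proton, c(0, 0, 0))[["phi_X"]])
    ),
    electrons_only_triad = list(
      description = "8-dim triad, kF = kX = 1, gamma2 = 1000, B = 50 uT",
      k_F = 1, k_X = 1, gamma2 = 1000, B_uT = 50,
      method = "full_liouville_resolvent", tolerance = 1e-8,
      phi_X = full_scavenging_yield(triad0, field_vector(50), "triplet12")
    )
  )
  path <- file.path(outdir, "fixtures.json")
  jsonlite::write_json(fixtures, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
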