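# Scenario files, packaged fixtures, random-scenario generation and
# reproduction reports.

SCENARIO_SCHEMA_VERSION <- "1.0"

scenario_required_fields <- list(
  order = c("p_first_solo", "p_second_solo", "p_second_comparative_observed"),
  disjunction = c("p_A", "p_B_given_A", "p_B_given_notA",
                  "p_B_unknown_observed"))

# field-level validation against the shipped schema
# (inst/schema/scenario.schema.json documents the same constraints)
validate_scenario_json <- function(obj, path = "<scenario>") {
  fail <- function(field, why) {
    stop(sprintf("scenario file '%s' invalid: field '%s' %s",
                 path, field, why), call. = FALSE)
  }
  if (is.null(obj$schema_version)) fail("schema_version", "is missing")
  if (is.null(obj$kind) || !obj$kind %in% names(scenario_required_fields)) {
    fail("kind", "must be 'order' or 'disjunction'")
  }
  if (is.null(obj$name) || !nzchar(obj$name)) fail("name", "is missing")
  if (isTRUE(obj$template)) return(invisible(obj))
  probs <- obj$probabilities
  if (is.null(probs)) fail("probabilities", "is missing")
  for (f in scenario_required_fields[[obj$kind]]) {
    v <- probs[[f]]
    if (is.null(v)) fail(paste0("probabilities.", f), "is missing")
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      fail(paste0("probabilities.", f), "must be a probability in [0, 1]")
    }
  }
  invisible(obj)
}

#' Load a scenario from a JSON file
#'
#' Validates against the shipped schema (see
#' `system.file("schema", "scenario.schema.json", package = "qcog")`) and
#' returns a typed scenario. Fitting is never performed implicitly. Template
#' files (probabilities absent, `"template": true`) return a
#' `scenario_template` stub.
#'
#' @param path Path to a scenario JSON file.
#' @return An [order_scenario()], [disjunction_scenario()], or
#'   `scenario_template` object.
#' @examples
#' load_scenario(system.file("extdata", "clinton_gore.json", package = "qcog"))
#' load_scenario(system.file("extdata", "prisoners_dilemma.json",
#'                           package = "qcog"))
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_scenario_json(obj, path)
  if (isTRUE(obj$template)) {
    return(structure(list(name = obj$name, kind = obj$kind,
                          provenance = obj$provenance),
                     class = "scenario_template"))
  }
  p <- obj$probabilities
  out <- if (obj$kind == "order") {
    order_scenario(obj$name, p$p_first_solo, p$p_second_solo,
                   p$p_second_comparative_observed,
                   p$p_first_comparative_observed)
  } else {
    disjunction_scenario(obj$name, p$p_A, p$p_B_given_A, p$p_B_given_notA,
                         p$p_B_unknown_observed)
  }
  attr(out, "provenance") <- obj$provenance
  attr(out, "fitted") <- obj$fitted
  out
}

#' @export
print.scenario_template <- function(x, ...) {
  cat(sprintf("<scenario_template '%s' (%s): no published rates>\n",
              x$name, x$kind))
  invisible(x)
}

#' Write a scenario to a JSON file
#'
#' Serializes the scenario (with `schema_version`, kind, probabilities,
#' optional fitted parameters and provenance note) so that
#' [load_scenario()] round-trips it exactly.
#'
#' @param scenario An `order_scenario` or `disjunction_scenario`.
#' @param path Output path.
#' @param fitted Optional named list/vector of fitted parameters to embed.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path, fitted = NULL) {
  kind <- if (inherits(scenario, "order_scenario")) "order"
          else if (inherits(scenario, "disjunction_scenario")) "disjunction"
          else stop("unsupported scenario object", call. = FALSE)
  probs <- scenario[setdiff(names(scenario), "name")]
  probs <- probs[!vapply(probs, is.null, logical(1))]
  obj <- list(schema_version = SCENARIO_SCHEMA_VERSION, kind = kind,
              name = scenario$name, probabilities = probs)
  prov <- attr(scenario, "provenance")
  if (!is.null(prov)) obj$provenance <- prov
  if (!is.null(fitted)) obj$fitted <- as.list(fitted)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a random, fittable scenario
#'
#' Draws scenario probabilities from documented uniform ranges, rejection
#' sampling until the fitting target is attainable, so that
#' [fit_order_model()] / [fit_phase()] always succeed on the result. Solo
#' and branch rates are drawn from U(0.15, 0.85) (order scenarios keep the
#' first solo rate at least 0.05 away from 1/2, where the phase is not
#' identifiable); the observed rate is drawn uniformly over the middle 80%
#' of the attainable interval. Identical seeds give identical scenarios.
#'
#' @param kind `"order"` or `"disjunction"`.
#' @param seed Integer seed.
#' @return An `order_scenario` or `disjunction_scenario`.
#' @examples
#' generate_random_scenario("disjunction", seed = 11)
#' @export
generate_random_scenario <- function(kind = c("order", "disjunction"), seed) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "order") {
      repeat {
        p1 <- stats::runif(1, 0.15, 0.85)
        if (abs(p1 - 0.5) >= 0.05) break
      }
      p2 <- stats::runif(1, 0.15, 0.85)
      rng <- comparative_range(prob_to_angle(p1), prob_to_angle(p2), p1)
      obs <- stats::runif(1, rng[1] + 0.1 * diff(rng),
                          rng[2] - 0.1 * diff(rng))
      order_scenario(sprintf("random_order_%d", as.integer(seed)),
                     p1, p2, obs)
    } else {
      p_A <- stats::runif(1, 0.15, 0.85)
      pBA <- stats::runif(1, 0.15, 0.85)
      pBnA <- stats::runif(1, 0.15, 0.85)
      sc0 <- disjunction_scenario("tmp", p_A, pBA, pBnA, 0.5)
      rng <- sort(c(closed_form_unknown(sc0, 0), closed_form_unknown(sc0, pi)))
      obs <- stats::runif(1, rng[1] + 0.1 * diff(rng),
                          rng[2] - 0.1 * diff(rng))
      disjunction_scenario(sprintf("random_disjunction_%d", as.integer(seed)),
                           p_A, pBA, pBnA, obs)
    }
  })
}

snl <- function(p, shots) sqrt(p * (1 - p) / shots)

#' Reproduce a scenario's observed rates from its circuits
#'
#' Fits the scenario's phase parameter, builds every condition variant,
#' evaluates each exactly (statevector) and — in `"shots"` mode — by seeded
#' sampling, and tabulates expected vs computed values. Exact deviations
#' are checked against 1e-9; sampled deviations are reported against five
#' shot-noise levels (\eqn{5\sqrt{p(1-p)/\mathrm{shots}}}).
#'
#' @param scenario An `order_scenario` or `disjunction_scenario`.
#' @param mode `"exact"` or `"shots"`.
#' @param shots Shots per circuit in `"shots"` mode.
#' @param seed Integer seed for sampling.
#' @return A `reproduction_report`: data frame with columns `quantity`,
#'   `expected`, `exact`, `sampled`, `exact_deviation`, `sampled_deviation`,
#'   `snl5`; attributes `scenario`, `mode`, `shots`, `seed`, `fitted`,
#'   `schema_version`, `package_version`, `ok`.
#' @examples
#' reproduce(load_scenario(system.file("extdata", "prisoners_dilemma.json",
#'                                     package = "qcog")))
#' @export
reproduce <- function(scenario, mode = c("exact", "shots"), shots = 10000L,
                      seed = 42L) {
  mode <- match.arg(mode)
  if (inherits(scenario, "order_scenario")) {
    fit <- fit_order_model(scenario)
    fitted <- coef(fit)
    expected <- c(p_first_solo = scenario$p_first_solo,
                  p_second_solo = scenario$p_second_solo,
                  p_second_comparative = scenario$p_second_comparative_observed)
    pr <- predict(fit, type = "circuit")
    exact <- pr[names(expected)]
    sampled <- rep(NA_real_, length(expected))
    if (mode == "shots") {
      c1 <- sample_counts(build_noncomparative_circuit(fit, "first"), shots,
                          seed = seed + 1L)
      c2 <- sample_counts(build_noncomparative_circuit(fit, "second"), shots,
                          seed = seed + 2L)
      cy <- sample_counts(build_comparative_circuit(fit, "yes"), shots,
                          seed = seed + 3L)
      cn <- sample_counts(build_comparative_circuit(fit, "no"), shots,
                          seed = seed + 4L)
      sampled <- c(conditional_from_counts(c1, ".", "0"),
                   conditional_from_counts(c2, ".", "0"),
                   reconstruct_comparative_rate(fit, cy, cn))
    }
  } else if (inherits(scenario, "disjunction_scenario")) {
    fit <- fit_phase(scenario)
    fitted <- coef(fit)["phi"]
    expected <- c(betray = scenario$p_B_given_A,
                  cooperate = scenario$p_B_given_notA,
                  unknown = scenario$p_B_unknown_observed)
    exact <- predict(fit, type = "circuit")[names(expected)]
    sampled <- rep(NA_real_, length(expected))
    if (mode == "shots") {
      sim <- simulate(fit, nsim = 1, seed = seed, shots = shots)
      sampled <- sim$rate[match(names(expected), sim$condition)]
    }
  } else {
    stop("'scenario' must be an order or disjunction scenario", call. = FALSE)
  }
  rep_df <- data.frame(
    quantity = names(expected),
    expected = as.numeric(expected),
    exact = as.numeric(exact),
    sampled = as.numeric(sampled),
    exact_deviation = abs(as.numeric(exact) - as.numeric(expected)),
    sampled_deviation = abs(as.numeric(sampled) - as.numeric(expected)),
    snl5 = 5 * snl(as.numeric(expected), shots),
    row.names = NULL)
  structure(rep_df, class = c("reproduction_report", "data.frame"),
            scenario = scenario$name, mode = mode,
            shots = if (mode == "shots") as.integer(shots) else NA_integer_,
            seed = if (mode == "shots") as.integer(seed) else NA_integer_,
            fitted = fitted,
            schema_version = SCENARIO_SCHEMA_VERSION,
            package_version = as.character(utils::packageVersion("qcog")),
            ok = all(rep_df$exact_deviation < 1e-9))
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(sprintf("Reproduction report: '%s' (mode %s", attr(x, "scenario"),
              attr(x, "mode")))
  if (!is.na(attr(x, "shots"))) {
    cat(sprintf(", %d shots, seed %d", attr(x, "shots"), attr(x, "seed")))
  }
  cat(sprintf("; qcog %s, schema %s)\n", attr(x, "package_version"),
              attr(x, "schema_version")))
  fitted <- attr(x, "fitted")
  cat("  fitted:", paste(sprintf("%s = %.6f", names(fitted), fitted),
                         collapse = ", "), "\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) if (is.numeric(col)) round(col, 6) else col)
  print(df, row.names = FALSE)
  cat(sprintf("  exact deviations all < 1e-9: %s\n", attr(x, "ok")))
  invisible(x)
}

#' Write a reproduction report as JSON
#'
#' Embeds seed, shots, schema and package versions alongside the table.
#'
#' @param report A `reproduction_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "reproduction_report"))
  jsonlite::write_json(
    list(scenario = attr(report, "scenario"), mode = attr(report, "mode"),
         shots = attr(report, "shots"), seed = attr(report, "seed"),
         fitted = as.list(attr(report, "fitted")),
         schema_version = attr(report, "schema_version"),
         package_version = attr(report, "package_version"),
         ok = attr(report, "ok"),
         rows = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
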