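#' Normalized relative sensitivity of a temperature-offset field
#'
#' For a baseline offset field theta and a field theta' obtained after
#' scaling one input parameter by (1 + delta), the per-unknown coefficient
#' is X_i = ((theta'_i - theta_i) / theta_i) / delta and the summary is the
#' arithmetic mean over included unknowns. Offsets with |theta_i| at or
#' below `floor` are excluded (the ratio diverges as theta -> 0) and
#' counted.
#'
#' @param theta_base,theta_pert baseline and perturbed offset fields
#'   (same length; temperature minus ambient, degC).
#' @param delta perturbation fraction (> 0).
#' @param floor exclusion threshold on |theta_base| (degC).
#' @return list with per-unknown `X` (NA where excluded), mean `X_bar`,
#'   `n_included`, `n_excluded`.
#' @export
relative_sensitivity <- function(theta_base, theta_pert, delta, floor = 0) {
  stopifnot(length(theta_base) == length(theta_pert), delta > 0, floor >= 0)
  ok <- abs(theta_base) > floor
  if (!any(ok)) stop("all baseline offsets are zero (or under the floor): sensitivity undefined")
  X <- rep(NA_real_, length(theta_base))
  X[ok] <- ((theta_pert[ok] - theta_base[ok]) / theta_base[ok]) / delta
  list(X = X, X_bar = mean(X[ok]),
       n_included = sum(ok), n_excluded = sum(!ok))
}

# offsets of the full temperature unknown vector (voxels + elements)
run_offsets <- function(run, include_elements = TRUE) {
  th <- run$heat$T_t - run$problem$thermal$T_inf
  if (include_elements)
    th <- c(th, run$heat$T_elem - run$problem$thermal$T_inf)
  th
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Re-solves the coupled model with each listed parameter scaled by
#' (1 + delta), one at a time, and reports the domain-average normalized
#' sensitivity of the temperature offset theta = T - T_inf. Flow-side
#' parameters (`k_a`, `k_v`, `alpha`, `gamma_a`, `gamma_v`, `mu`) trigger a
#' full flow + heat re-solve; heat-side parameters (`h_inf`, `h_b`,
#' `qdot_m`) reuse the baseline flow solution; `theta_in` perturbs the
#' inlet offset (T_in = T_inf + (1 + delta) * (T_in - T_inf)). A failed
#' perturbed solve is recorded in its row and the analysis continues.
#'
#' @param problem a `hemo_problem`.
#' @param parameters character vector of parameter names (see above).
#' @param delta perturbation fraction (default 0.01, i.e. +1%).
#' @param include_elements include vessel-element temperatures in the
#'   average (default TRUE).
#' @param theta_floor exclusion threshold on |theta| (degC).
#' @param method,tol solver settings.
#' @return object of class `oat_sensitivity`: data frame with columns
#'   `parameter`, `delta`, `X_bar`, `n_included`, `n_excluded`, `error`;
#'   the baseline `hemo_run` is attached as an attribute.
#' @export
oat_analysis <- function(problem,
                         parameters = c("theta_in", "h_inf", "alpha", "k_a",
                                        "k_v", "gamma_a", "gamma_v", "h_b"),
                         delta = 0.01, include_elements = TRUE,
                         theta_floor = 1e-6, method = "auto", tol = 1e-8) {
  flow_names <- c("k_a", "k_v", "alpha", "gamma_a", "gamma_v", "mu")
  heat_names <- c("h_inf", "h_b", "qdot_m")
  base <- run_simulation(problem, method = method, tol = tol, quiet = TRUE)
  theta0 <- run_offsets(base, include_elements)

  rows <- lapply(parameters, function(par) {
    res <- tryCatch({
      p2 <- problem
      reuse_flow <- NULL
      if (par %in% flow_names) {
        p2$flow[[par]] <- p2$flow[[par]] * (1 + delta)
      } else if (par %in% heat_names) {
        p2$thermal[[par]] <- p2$thermal[[par]] * (1 + delta)
        reuse_flow <- base$flow
      } else if (par == "theta_in") {
        p2$thermal$T_in <- p2$thermal$T_inf +
          (1 + delta) * (p2$thermal$T_in - p2$thermal$T_inf)
        reuse_flow <- base$flow
      } else stop("unknown parameter: ", par)
      # flow-parameter perturbations must rebuild the flow system with the
      # perturbed params even when reusing the coupling map
      pert <- run_simulation(p2, coupling = base$coupling, flow = reuse_flow,
                             method = method, tol = tol, quiet = TRUE)
      s <- relative_sensitivity(theta0, run_offsets(pert, include_elements),
                                delta, floor = theta_floor)
      data.frame(parameter = par, delta = delta, X_bar = s$X_bar,
                 n_included = s$n_included, n_excluded = s$n_excluded,
                 error = NA_character_)
    }, error = function(e)
      data.frame(parameter = par, delta = delta, X_bar = NA_real_,
                 n_included = NA_integer_, n_excluded = NA_integer_,
                 error = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  class(out) <- c("oat_sensitivity", "data.frame")
  out
}

#' @export
print.oat_sensitivity <- function(x, ...) {
  cat("One-at-a-time sensitivity of the temperature offset (theta = T - T_inf)\n")
  df <- as.data.frame(x)
  df$X_bar <- signif(df$X_bar, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
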