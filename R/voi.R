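## evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Network-blind counterpart of a decision model
#'
#' Returns the same model with every link strength set to zero: the
#' planner's view of the system when no social network information is
#' available, i.e. actors assumed independent. Idempotent; all other
#' parameters are unchanged.
#'
#' @param model A [decision_model()].
#' @return A [decision_model()] with an empty influence structure.
#' @export
uninformed_model <- function(model) {
  net <- model$network
  net$edges$u_r <- rep(0, nrow(net$edges))
  net$edges$u_d <- rep(0, nrow(net$edges))
  decision_model(net, model$species, model$params,
                 discount = model$discount, cost = model$cost)
}

new_voi_result <- function(v_informed, v_uninformed, first_informed,
                           first_uninformed) {
  eps <- 1e-12
  flagged <- FALSE
  if (abs(v_informed) < eps && abs(v_uninformed) < eps) {
    pct <- 0
  } else if (v_uninformed <= 0 && v_informed > 0) {
    pct <- NA_real_
    flagged <- TRUE
  } else {
    pct <- 100 * (v_informed - v_uninformed) / v_uninformed
  }
  structure(
    list(v_informed = v_informed, v_uninformed = v_uninformed,
         voi_percent = pct, voi_abs = v_informed - v_uninformed,
         flagged = flagged,
         first_action_informed = first_informed,
         first_action_uninformed = first_uninformed),
    class = "voi_result"
  )
}

#' Value of social network information
#'
#' Solves the model twice: once with the true network (informed) and once
#' network-blind ([uninformed_model()]), then evaluates both resulting
#' policies exactly under the *true* dynamics and reads their values at the
#' all-available initial state. The value of information is the percent
#' improvement `100 (v_informed - v_uninformed) / v_uninformed`; it is 0
#' when the two models coincide (e.g. all strengths zero) and nonnegative
#' up to linear-solve roundoff because the informed policy is optimal under
#' the true dynamics. If `v_uninformed <= 0 < v_informed` the percent is
#' undefined and the result is flagged, with the absolute difference still
#' reported.
#'
#' @param model A [decision_model()].
#' @param uninformed_policy Optional precomputed network-blind `policy`
#'   (the blind planner does not depend on the network, so it can be cached
#'   across link-strength settings).
#' @param P Optional precomputed true-model transition matrices.
#' @return An object of class `voi_result` with fields `v_informed`,
#'   `v_uninformed`, `voi_percent`, `voi_abs`, `flagged`,
#'   `first_action_informed`, `first_action_uninformed` (actions at the
#'   all-available state; 0 = no-op, i = target node i).
#' @export
compute_voi <- function(model, uninformed_policy = NULL, P = NULL) {
  if (is.null(P)) P <- transition_matrices(model)
  sol_inf <- solve_decision_model(model, P = P)
  if (is.null(uninformed_policy)) {
    uninformed_policy <- solve_decision_model(uninformed_model(model))$policy
  }
  v_unf <- evaluate_policy_exact(model, uninformed_policy, P = P)$v[1]
  new_voi_result(sol_inf$value$v[1], v_unf,
                 sol_inf$policy$actions[1], uninformed_policy$actions[1])
}

#' @export
print.voi_result <- function(x, ...) {
  cat("<voi_result>\n")
  cat("  informed value   :", signif(x$v_informed, 6), "\n")
  cat("  uninformed value :", signif(x$v_uninformed, 6), "\n")
  if (x$flagged) {
    cat("  VoI percent undefined (flagged); absolute difference",
        signif(x$voi_abs, 6), "\n")
  } else {
    cat("  VoI:", signif(x$voi_percent, 4), "%\n")
  }
  invisible(x)
}

#' @export
#' @method tidy voi_result
tidy.voi_result <- function(x, ...) {
  tibble::tibble(
    v_informed = x$v_informed, v_uninformed = x$v_uninformed,
    voi_percent = x$voi_percent, voi_abs = x$voi_abs, flagged = x$flagged,
    first_action_informed = x$first_action_informed,
    first_action_uninformed = x$first_action_uninformed
  )
}

#' Specify a motif-by-nestedness-by-strength experiment grid
#'
#' Defines the full factorial simulation study: for every combination of
#' motif, target nestedness `phi`, reserve-link strength `u_r`,
#' development-link strength `u_d` and replicate, a species pool is drawn
#' and the value of network information computed. Replicate species pools
#' are seeded deterministically from `master_seed` and `(phi, replicate)`
#' only, so the same pool is reused across strengths and motifs (paired
#' comparisons) and the network-blind planner, which depends only on the
#' pool, is solved once per pool.
#'
#' @param motifs Character vector of motif kinds.
#' @param phi_values,u_r_values,u_d_values Numeric grids.
#' @param n_species,n_sites Species pool dimensions.
#' @param p_d,p_r Behavioral probabilities.
#' @param replicates Species-pool replicates per combination.
#' @param discount,cost Planner settings.
#' @param master_seed Integer master seed.
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(motifs = c("ring", "line", "ring_star", "wheel",
                                       "star"),
                            phi_values = seq(0.1, 1, by = 0.1),
                            u_r_values = seq(0, 1, by = 0.1),
                            u_d_values = seq(0, 1, by = 0.1),
                            n_species = 20, n_sites = 6,
                            p_d = 0.2, p_r = 0.2, replicates = 5,
                            discount = 0.95, cost = 0.1, master_seed = 1) {
  stopifnot(length(motifs) >= 1, length(phi_values) >= 1,
            length(u_r_values) >= 1, length(u_d_values) >= 1,
            replicates >= 1)
  structure(
    list(motifs = motifs, phi_values = phi_values, u_r_values = u_r_values,
         u_d_values = u_d_values, n_species = n_species, n_sites = n_sites,
         p_d = p_d, p_r = p_r, replicates = replicates, discount = discount,
         cost = cost, master_seed = as.integer(master_seed)),
    class = "experiment_grid"
  )
}

## deterministic per-pool seed, kept below 2^31
pool_seed <- function(master_seed, phi_index, replicate) {
  (master_seed %% 100000L) * 20011L + phi_index * 211L + replicate
}

#' Run the experiment grid
#'
#' Executes [compute_voi()] for every grid cell. Per-instance values come
#' from exact policy evaluation, so conditional on the replicate species
#' pools the records are deterministic; re-running with the same
#' `master_seed` reproduces them bit for bit. Individual solver failures
#' are recorded in the `error` column rather than aborting the run.
#'
#' @param grid An [experiment_grid()].
#' @param progress Print one line per motif.
#' @return A tibble with one row per (motif, phi, u_r, u_d, replicate):
#'   achieved nestedness `score` and feasibility flag, informed and
#'   uninformed values and first actions (0-based `target` ids, `NA` =
#'   no-op), `voi_percent`, and logical flags for whether each first action
#'   targets a most species-rich site (`richest_*`) or a maximum-closeness
#'   node (`central_*`).
#' @export
run_voi_grid <- function(grid, progress = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  params <- behavior_params(grid$p_d, grid$p_r)

  ## replicate species pools, shared across motifs and strengths
  pools <- list()
  for (pi in seq_along(grid$phi_values)) {
    for (rep in seq_len(grid$replicates)) {
      seed <- pool_seed(grid$master_seed, pi, rep)
      pools[[paste(pi, rep)]] <- with_seed(
        seed,
        generate_species_distribution(grid$n_species, grid$n_sites,
                                      grid$phi_values[pi])
      )
    }
  }

  ## network-blind planner per pool (independent of motif and strengths)
  blind_net <- actor_network(grid$n_sites)
  P_blind <- NULL
  blind <- list()
  for (key in names(pools)) {
    m_u <- decision_model(blind_net, pools[[key]], params,
                          discount = grid$discount, cost = grid$cost)
    if (is.null(P_blind)) P_blind <- transition_matrices(m_u)
    blind[[key]] <- solve_decision_model(m_u, P = P_blind)
  }

  rows <- list()
  for (motif in grid$motifs) {
    if (progress) message("motif: ", motif)
    net1 <- motif_network(motif, grid$n_sites, 0, 0)
    cc <- closeness_centrality(net1)
    central_set <- which(cc >= max(cc) - 1e-12)
    for (u_r in grid$u_r_values) {
      for (u_d in grid$u_d_values) {
        net <- motif_network(motif, grid$n_sites, u_r, u_d)
        linkless <- u_r == 0 && u_d == 0
        P <- NULL
        for (pi in seq_along(grid$phi_values)) {
          for (rep in seq_len(grid$replicates)) {
            key <- paste(pi, rep)
            sp <- pools[[key]]
            richness <- rowSums(sp$incidence)
            rich_set <- which(richness >= max(richness) - 1e-12)
            rec <- tibble::tibble(
              motif = motif, phi = grid$phi_values[pi], u_r = u_r,
              u_d = u_d, replicate = rep,
              score = attr(sp, "score"), feasible = attr(sp, "feasible"),
              seed = pool_seed(grid$master_seed, pi, rep)
            )
            res <- tryCatch({
              if (linkless) {
                sol_u <- blind[[key]]
                v <- sol_u$value$v[1]
                a <- sol_u$policy$actions[1]
                list(v_inf = v, v_unf = v, pct = 0, flagged = FALSE,
                     a_inf = a, a_unf = a)
              } else {
                model <- decision_model(net, sp, params,
                                        discount = grid$discount,
                                        cost = grid$cost)
                if (is.null(P)) P <- transition_matrices(model)
                voi <- compute_voi(model,
                                   uninformed_policy = blind[[key]]$policy,
                                   P = P)
                list(v_inf = voi$v_informed, v_unf = voi$v_uninformed,
                     pct = voi$voi_percent, flagged = voi$flagged,
                     a_inf = voi$first_action_informed,
                     a_unf = voi$first_action_uninformed)
              }
            }, error = function(e) e)
            if (inherits(res, "error")) {
              rec$v_informed <- NA_real_
              rec$v_uninformed <- NA_real_
              rec$voi_percent <- NA_real_
              rec$flagged <- NA
              rec$target_informed <- NA_integer_
              rec$target_uninformed <- NA_integer_
              rec$richest_informed <- NA
              rec$richest_uninformed <- NA
              rec$central_informed <- NA
              rec$central_uninformed <- NA
              rec$error <- conditionMessage(res)
            } else {
              rec$v_informed <- res$v_inf
              rec$v_uninformed <- res$v_unf
              rec$voi_percent <- res$pct
              rec$flagged <- res$flagged
              rec$target_informed <- if (res$a_inf == 0) NA_integer_ else
                res$a_inf - 1L
              rec$target_uninformed <- if (res$a_unf == 0) NA_integer_ else
                res$a_unf - 1L
              rec$richest_informed <- res$a_inf %in% rich_set
              rec$richest_uninformed <- res$a_unf %in% rich_set
              rec$central_informed <- res$a_inf %in% central_set
              rec$central_uninformed <- res$a_unf %in% central_set
              rec$error <- NA_character_
            }
            rows[[length(rows) + 1L]] <- rec
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "grid") <- grid
  out
}

## percentile bootstrap CI for a mean
boot_ci_mean <- function(x, n_boot = 999, conf = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  means <- vapply(seq_len(n_boot), function(i) {
    mean(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  unname(stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Summarize grid records per motif
#'
#' Per-motif mean value of information with a percentile-bootstrap
#' confidence interval, plus the fractions of instances whose first action
#' targets a most species-rich site (informed and uninformed planners) and
#' a maximum-closeness node. Ties count as satisfied when the targeted site
#' attains the maximum.
#'
#' @param records Output of [run_voi_grid()].
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @return A tibble with one row per motif, of class `voi_grid_summary`.
#' @export
summarize_voi_grid <- function(records, n_boot = 999, conf = 0.95) {
  stopifnot(nrow(records) > 0)
  out <- records |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_voi = mean(.data$voi_percent, na.rm = TRUE),
      ci_lo = boot_ci_mean(.data$voi_percent, n_boot, conf)[1],
      ci_hi = boot_ci_mean(.data$voi_percent, n_boot, conf)[2],
      max_voi = max(.data$voi_percent, na.rm = TRUE),
      frac_richest_informed = mean(.data$richest_informed),
      frac_richest_uninformed = mean(.data$richest_uninformed),
      frac_central_informed = mean(.data$central_informed),
      frac_central_uninformed = mean(.data$central_uninformed),
      .groups = "drop"
    )
  class(out) <- c("voi_grid_summary", class(out))
  out
}

#' Conditional VoI means by parameter tercile
#'
#' Splits the grid records into terciles of either the achieved nestedness
#' score or the combined link strength `(u_r + u_d) / 2` and reports the
#' mean value of information per motif and tercile.
#'
#' @param records Output of [run_voi_grid()].
#' @param which `"phi"` (achieved nestedness score) or `"strength"`.
#' @return A tibble with columns `motif`, `tercile`, `n`, `mean_voi`.
#' @export
voi_tercile_means <- function(records, which = c("phi", "strength")) {
  which <- match.arg(which)
  records <- dplyr::filter(records, is.na(.data$error))
  key <- if (which == "phi") records$score else
    (records$u_r + records$u_d) / 2
  records$tercile <- dplyr::ntile(key, 3)
  records |>
    dplyr::group_by(.data$motif, .data$tercile) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_voi = mean(.data$voi_percent, na.rm = TRUE),
                     .groups = "drop")
}
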