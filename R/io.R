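#' Read and write actor networks as edge-list CSV
#'
#' The on-disk format has a mandatory header `source,target,u_r,u_d` with
#' 0-based integer node ids and one row per undirected link. Readers reject
#' rather than coerce: malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param n_nodes Total node count (isolated nodes cannot be inferred from
#'   an edge list); defaults to `max(id) + 1`.
#' @param labels Optional node labels.
#' @return An [actor_network()].
#' @export
read_network <- function(path, n_nodes = NULL, labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("source", "target", "u_r", "u_d")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("Network file must have header 'source,target,u_r,u_d'; got '",
         paste(names(df), collapse = ","), "'.", call. = FALSE)
  }
  bad <- which(!vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    is.numeric(r$source) && is.numeric(r$target) &&
      r$source == floor(r$source) && r$target == floor(r$target) &&
      r$source >= 0 && r$target >= 0 && r$source != r$target &&
      !is.na(r$u_r) && !is.na(r$u_d) &&
      r$u_r >= 0 && r$u_r <= 1 && r$u_d >= 0 && r$u_d <= 1
  }, logical(1)))
  if (length(bad) > 0) {
    stop("Malformed network rows at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " of ", path, " (need 0-based ids, no self-links, strengths in ",
         "[0,1]).", call. = FALSE)
  }
  if (is.null(n_nodes)) n_nodes <- max(df$source, df$target) + 1L
  actor_network(
    n_nodes,
    data.frame(from = df$source + 1L, to = df$target + 1L,
               u_r = df$u_r, u_d = df$u_d),
    labels = labels
  )
}

#' @param net An [actor_network()].
#' @rdname read_network
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "actor_network"))
  readr::write_csv(
    tibble::tibble(source = net$edges$from - 1L, target = net$edges$to - 1L,
                   u_r = net$edges$u_r, u_d = net$edges$u_d),
    path
  )
  invisible(path)
}

#' Read and write species incidence CSV
#'
#' Rows are sites (in node order), columns are species, entries 0/1, with a
#' mandatory header row of species names. Non-binary entries are rejected
#' with their line numbers.
#'
#' @param path File path.
#' @return A [species_distribution()].
#' @export
read_incidence <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  bad <- which(apply(m, 1, function(r) any(is.na(r)) || !all(r %in% c(0, 1))))
  if (length(bad) > 0) {
    stop("Non-binary incidence entries at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, ".", call. = FALSE)
  }
  species_distribution(m, species_names = colnames(df))
}

#' @param species A [species_distribution()].
#' @rdname read_incidence
#' @export
write_incidence <- function(species, path) {
  stopifnot(inherits(species, "species_distribution"))
  inc <- species$incidence
  colnames(inc) <- colnames(inc) %||% paste0("sp", seq_len(ncol(inc)))
  utils::write.csv(as.data.frame(inc), path, row.names = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(
    params = list(p_d = 0.2, p_r = 0.2, u_r = 0.5, u_d = 0.5),
    planner = list(discount = 0.95, cost = 0.1, tol = 1e-6),
    grid = list(
      motifs = c("ring", "line", "ring_star", "wheel", "star"),
      phi_values = seq(0.1, 1, by = 0.1),
      u_r_values = seq(0, 1, by = 0.1),
      u_d_values = seq(0, 1, by = 0.1),
      n_species = 20, replicates = 5
    ),
    species = list(n_species = 20, phi = 0.5),
    out_dir = ".",
    master_seed = 1L
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Validates the schema before any computation: behavioral probabilities
#' and link strengths must be in `[0, 1]`, the discount in `(0, 1)`, the
#' cost nonnegative, and motif names from the known set. Unspecified fields
#' take documented defaults. Every run command writes a resolved copy of
#' its configuration next to its outputs.
#'
#' @param path Path to a YAML file, or a list already in config shape.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- merge_config(config_defaults(), user)
  p <- cfg$params
  if (any(unlist(p[c("p_d", "p_r", "u_r", "u_d")]) < 0) ||
      any(unlist(p[c("p_d", "p_r", "u_r", "u_d")]) > 1)) {
    stop("Config: probabilities and link strengths must lie in [0, 1].",
         call. = FALSE)
  }
  if (cfg$planner$discount <= 0 || cfg$planner$discount >= 1) {
    stop("Config: planner discount must lie in (0, 1).", call. = FALSE)
  }
  if (cfg$planner$cost < 0) {
    stop("Config: intervention cost must be nonnegative.", call. = FALSE)
  }
  if (!all(cfg$grid$motifs %in% c("ring", "line", "ring_star", "wheel",
                                  "star"))) {
    stop("Config: unknown motif in grid.motifs.", call. = FALSE)
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

## assemble the model a config describes (single-instance commands)
config_model <- function(cfg) {
  if (!is.null(cfg$network_file)) {
    net <- read_network(cfg$network_file)
  } else {
    motif <- cfg$motif %||% "star"
    net <- motif_network(motif, cfg$n_nodes %||% 6,
                         u_r = cfg$params$u_r, u_d = cfg$params$u_d)
  }
  if (!is.null(cfg$incidence_file)) {
    sp <- read_incidence(cfg$incidence_file)
  } else {
    sp <- with_seed(cfg$master_seed, generate_species_distribution(
      cfg$species$n_species, net$n_nodes, cfg$species$phi))
  }
  decision_model(net, sp, behavior_params(cfg$params$p_d, cfg$params$p_r),
                 discount = cfg$planner$discount, cost = cfg$planner$cost)
}

write_resolved_config <- function(cfg, out_dir, name) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir,
                                           paste0(name, "-config.yml")))
}

#' Run commands: solve, VoI, grid, case study
#'
#' Batch entry points mirroring the `netreserve` command-line script. Each
#' takes a config (YAML path or list, see [read_run_config()]), writes its
#' artifacts plus a resolved-config copy into `out_dir`, and returns its
#' result invisibly. `run_solve()` writes the optimal policy and value
#' table; `run_voi()` the value-of-information JSON; `run_grid()` the
#' per-instance records and per-motif summary CSVs; `run_casestudy()` the
#' fishery-style case study (synthetic fixture unless files are supplied)
#' with the optimal intervention sequences with and without network
#' information.
#'
#' @param config Config path or list.
#' @return Invisibly: the solution, VoI result, records tibble, or case
#'   study list respectively.
#' @export
run_solve <- function(config) {
  cfg <- read_run_config(config)
  model <- config_model(cfg)
  sol <- solve_decision_model(model, tol = cfg$planner$tol)
  write_resolved_config(cfg, cfg$out_dir, "solve")
  readr::write_csv(tidy(sol), file.path(cfg$out_dir, "policy.csv"))
  invisible(sol)
}

#' @rdname run_solve
#' @export
run_voi <- function(config) {
  cfg <- read_run_config(config)
  model <- config_model(cfg)
  voi <- compute_voi(model)
  write_resolved_config(cfg, cfg$out_dir, "voi")
  jsonlite::write_json(as.list(tidy(voi)),
                       file.path(cfg$out_dir, "voi.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(voi)
}

#' @rdname run_solve
#' @export
run_grid <- function(config) {
  cfg <- read_run_config(config)
  g <- cfg$grid
  grid <- experiment_grid(
    motifs = g$motifs, phi_values = g$phi_values,
    u_r_values = g$u_r_values, u_d_values = g$u_d_values,
    n_species = g$n_species, n_sites = cfg$n_nodes %||% 6,
    p_d = cfg$params$p_d, p_r = cfg$params$p_r,
    replicates = g$replicates, discount = cfg$planner$discount,
    cost = cfg$planner$cost, master_seed = cfg$master_seed
  )
  records <- run_voi_grid(grid)
  write_resolved_config(cfg, cfg$out_dir, "grid")
  readr::write_csv(records, file.path(cfg$out_dir, "grid-records.csv"))
  readr::write_csv(summarize_voi_grid(records),
                   file.path(cfg$out_dir, "grid-summary.csv"))
  invisible(records)
}

#' @rdname run_solve
#' @export
run_casestudy <- function(config) {
  cfg <- read_run_config(config)
  if (!is.null(cfg$network_file) && !is.null(cfg$incidence_file)) {
    net <- read_network(cfg$network_file)
    sp <- read_incidence(cfg$incidence_file)
  } else {
    fix <- make_fishery_fixture(seed = cfg$master_seed)
    net <- fix$network
    sp <- fix$species
  }
  model <- decision_model(net, sp,
                          behavior_params(cfg$params$p_d, cfg$params$p_r),
                          discount = cfg$planner$discount,
                          cost = cfg$planner$cost)
  cs <- case_study(model)
  write_resolved_config(cfg, cfg$out_dir, "casestudy")
  readr::write_csv(cs$sequences, file.path(cfg$out_dir,
                                           "casestudy-sequences.csv"))
  jsonlite::write_json(as.list(tidy(cs$voi)),
                       file.path(cfg$out_dir, "casestudy-voi.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cs)
}
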