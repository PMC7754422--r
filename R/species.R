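#' Species-by-site incidence matrices
#'
#' A `species_distribution` stores a binary incidence matrix with one row
#' per site (network node) and one column per species. A species' range
#' size is the number of sites it occupies; every species must occupy at
#' least one site.
#'
#' @param incidence Binary matrix, rows = sites, columns = species.
#' @param site_names,species_names Optional dimension names.
#' @return An object of class `species_distribution` with elements
#'   `incidence` and `range_sizes`.
#' @export
species_distribution <- function(incidence, site_names = NULL,
                                 species_names = NULL) {
  incidence <- as.matrix(incidence)
  if (nrow(incidence) == 0) {
    stop("Incidence matrix must have at least one site row.", call. = FALSE)
  }
  if (!all(incidence %in% c(0, 1))) {
    stop("Incidence entries must be 0 or 1.", call. = FALSE)
  }
  storage.mode(incidence) <- "integer"
  if (any(colSums(incidence) == 0)) {
    stop("Every species must occupy at least one site.", call. = FALSE)
  }
  if (!is.null(site_names)) rownames(incidence) <- site_names
  if (!is.null(species_names)) colnames(incidence) <- species_names
  structure(
    list(incidence = incidence, range_sizes = colSums(incidence)),
    class = "species_distribution"
  )
}

#' @export
print.species_distribution <- function(x, ...) {
  cat("<species_distribution> ", nrow(x$incidence), " sites x ",
      ncol(x$incidence), " species, ", sum(x$incidence), " presences\n",
      sep = "")
  cat("discrepancy d = ", discrepancy_index(x),
      ", nestedness score = ", round(nestedness_score(x), 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy species_distribution
tidy.species_distribution <- function(x, ...) {
  inc <- x$incidence
  sites <- rownames(inc) %||% paste0("site", seq_len(nrow(inc)) - 1L)
  spp <- colnames(inc) %||% paste0("sp", seq_len(ncol(inc)))
  tibble::tibble(
    site = rep(sites, times = ncol(inc)),
    species = rep(spp, each = nrow(inc)),
    present = as.integer(inc)
  )
}

#' Draw per-species range sizes
#'
#' Each species' range size (number of occupied sites) is drawn
#' independently and uniformly from `{1, ..., n_sites}`, so that the
#' species pool spans narrow endemics through ubiquitous species. Uses the
#' current R random number stream.
#'
#' @param n_species,n_sites Positive counts.
#' @return Integer vector of length `n_species`.
#' @export
sample_range_sizes <- function(n_species, n_sites) {
  stopifnot(n_species >= 1, n_sites >= 1)
  sample.int(n_sites, n_species, replace = TRUE)
}

## packing count: presences outside the maximally packed matrix with the
## same row sums; species ranked by decreasing total incidence, ties broken
## by original column index (deterministic, no search over orderings)
packing_discrepancy <- function(inc) {
  ord <- order(colSums(inc), decreasing = TRUE)  # order() is stable
  inc <- inc[, ord, drop = FALSE]
  r <- rowSums(inc)
  sum(vapply(seq_len(nrow(inc)), function(i) {
    if (r[i] == 0) return(0L)
    as.integer(r[i] - sum(inc[i, seq_len(r[i])]))
  }, integer(1)))
}

#' Brualdi-Sanderson discrepancy index
#'
#' Sites are ordered by decreasing richness and species by decreasing
#' incidence (ties broken by original index); the index `d` counts the
#' presences lying outside the maximally packed matrix with the same row
#' sums. `d = 0` iff the matrix is perfectly nested under this ordering.
#'
#' @param x A [species_distribution()] or binary sites-by-species matrix.
#' @return Nonnegative integer.
#' @export
discrepancy_index <- function(x) {
  inc <- if (inherits(x, "species_distribution")) x$incidence else as.matrix(x)
  if (length(inc) == 0) stop("Empty matrix.", call. = FALSE)
  packing_discrepancy(inc)
}

#' Normalized nestedness score
#'
#' `1 - d / F` where `d` is the discrepancy index and `F` the total number
#' of presences: 1 for a perfectly nested matrix, smaller for increasingly
#' un-nested ones. This is the internal, monotone stand-in for a nestedness
#' level on `[0, 1]` used by the generator.
#'
#' @inheritParams discrepancy_index
#' @return Value in `[0, 1]`.
#' @export
nestedness_score <- function(x) {
  inc <- if (inherits(x, "species_distribution")) x$incidence else as.matrix(x)
  1 - discrepancy_index(inc) / sum(inc)
}

#' Generate a species distribution with controlled nestedness
#'
#' Starts from the perfectly nested arrangement (species `s` occupies the
#' first `range_sizes[s]` sites) and applies range-size-preserving
#' single-presence moves, greedily accepted when they bring the
#' [nestedness_score()] closer to the target `phi`. Stops when the score is
#' within `tol` of `phi`, after `max_moves` proposals, or after `stall`
#' consecutive rejections. Low targets produce maximally un-nested
#' (beyond-random) configurations; when `phi` is unattainable under the
#' drawn range sizes the best achieved configuration is returned with
#' `feasible = FALSE` (never silently).
#'
#' @param n_species,n_sites Pool dimensions.
#' @param phi Target nestedness in `(0, 1]`.
#' @param range_sizes Optional integer vector of per-species range sizes;
#'   drawn with [sample_range_sizes()] when omitted.
#' @param tol Score tolerance for declaring the target met.
#' @param max_moves Proposal cap.
#' @param stall Stop after this many consecutive rejected proposals.
#' @return A [species_distribution()] with attributes `score` (achieved
#'   [nestedness_score()]), `phi` (target), `feasible` (logical) and
#'   `moves` (accepted move count).
#' @export
generate_species_distribution <- function(n_species, n_sites, phi,
                                          range_sizes = NULL, tol = 0.02,
                                          max_moves = 10000, stall = 500) {
  if (length(phi) != 1 || phi <= 0 || phi > 1) {
    stop("`phi` must lie in (0, 1].", call. = FALSE)
  }
  if (is.null(range_sizes)) {
    range_sizes <- sample_range_sizes(n_species, n_sites)
  }
  stopifnot(length(range_sizes) == n_species,
            all(range_sizes >= 1), all(range_sizes <= n_sites))

  inc <- matrix(0L, n_sites, n_species)
  for (s in seq_len(n_species)) inc[seq_len(range_sizes[s]), s] <- 1L
  total <- sum(inc)
  score <- 1 - packing_discrepancy(inc) / total
  accepted <- 0L
  rejected_run <- 0L
  movable <- which(range_sizes >= 1 & range_sizes < n_sites)

  if (length(movable) > 0) {
    for (k in seq_len(max_moves)) {
      if (abs(score - phi) <= tol || rejected_run >= stall) break
      sp <- movable[sample.int(length(movable), 1L)]
      occ <- which(inc[, sp] == 1L)
      emp <- which(inc[, sp] == 0L)
      i <- occ[sample.int(length(occ), 1L)]
      j <- emp[sample.int(length(emp), 1L)]
      inc[i, sp] <- 0L
      inc[j, sp] <- 1L
      new_score <- 1 - packing_discrepancy(inc) / total
      if (abs(new_score - phi) < abs(score - phi)) {
        score <- new_score
        accepted <- accepted + 1L
        rejected_run <- 0L
      } else {
        inc[i, sp] <- 1L
        inc[j, sp] <- 0L
        rejected_run <- rejected_run + 1L
      }
    }
  }
  ## randomize which network node carries which nestedness rank: the seed
  ## arrangement is built on sites in index order, and without this
  ## relabeling site 1 would be the richest site in (almost) every draw,
  ## confounding nestedness rank with node identity
  inc <- inc[sample.int(n_sites), , drop = FALSE]
  out <- species_distribution(inc)
  attr(out, "score") <- score
  attr(out, "phi") <- phi
  attr(out, "feasible") <- abs(score - phi) <= tol
  attr(out, "moves") <- accepted
  out
}

## TRUE if any 2x2 checkerboard submatrix exists
has_checkerboard <- function(inc) {
  cp <- crossprod(inc)              # co-occurrence counts between species
  r <- colSums(inc)
  ## species pair (a, b) admits a swap iff a occupies a site b misses and
  ## vice versa: cp[a, b] < r[a] and cp[a, b] < r[b]
  ok <- (cp < r) & (cp < matrix(r, nrow(cp), ncol(cp), byrow = TRUE))
  diag(ok) <- FALSE
  any(ok)
}

#' Nestedness permutation test
#'
#' Compares the observed discrepancy index with a null distribution of
#' matrices generated by checkerboard swaps (sequential trial swaps of 2x2
#' submatrices `10/01 <-> 01/10`), which preserve both row and column sums
#' exactly. The one-sided p-value `(1 + #{d_null <= d_obs}) / (n_perm + 1)`
#' is small when the matrix is more nested than expected under the
#' fixed-marginal null. A matrix with no swappable checkerboard unit has a
#' degenerate null (every permutation equals the observed matrix) and is
#' reported with `p_value = 1` and `degenerate = TRUE`.
#'
#' @inheritParams discrepancy_index
#' @param n_perm Number of null matrices (at least 99).
#' @param burn_in,thin Trial swaps before the first sample and between
#'   samples; defaults scale with the number of presences.
#' @return An object of class `nestedness_test` with fields `discrepancy`,
#'   `score`, `p_value`, `degenerate`, `n_perm` and the vector of null
#'   discrepancies.
#' @export
nestedness_null_test <- function(x, n_perm = 999, burn_in = NULL,
                                 thin = NULL) {
  inc <- if (inherits(x, "species_distribution")) x$incidence else as.matrix(x)
  if (n_perm < 99) stop("`n_perm` must be at least 99.", call. = FALSE)
  d_obs <- packing_discrepancy(inc)
  total <- sum(inc)
  if (is.null(burn_in)) burn_in <- 10L * total
  if (is.null(thin)) thin <- 2L * total

  degenerate <- !has_checkerboard(inc)
  if (degenerate) {
    null_d <- rep(d_obs, n_perm)
  } else {
    cur <- inc
    nr <- nrow(cur)
    nc <- ncol(cur)
    null_d <- integer(n_perm)
    do_swaps <- function(m, k) {
      rows <- matrix(replicate(k, sample.int(nr, 2L)), nrow = 2L)
      cols <- matrix(replicate(k, sample.int(nc, 2L)), nrow = 2L)
      for (t in seq_len(k)) {
        r1 <- rows[1, t]; r2 <- rows[2, t]
        c1 <- cols[1, t]; c2 <- cols[2, t]
        a <- m[r1, c1]; b <- m[r1, c2]; cc <- m[r2, c1]; dd <- m[r2, c2]
        if (a + dd == 2L && b + cc == 0L) {
          m[r1, c1] <- 0L; m[r2, c2] <- 0L; m[r1, c2] <- 1L; m[r2, c1] <- 1L
        } else if (a + dd == 0L && b + cc == 2L) {
          m[r1, c1] <- 1L; m[r2, c2] <- 1L; m[r1, c2] <- 0L; m[r2, c1] <- 0L
        }
      }
      m
    }
    cur <- do_swaps(cur, burn_in)
    for (p in seq_len(n_perm)) {
      cur <- do_swaps(cur, thin)
      null_d[p] <- packing_discrepancy(cur)
    }
  }
  p <- (1 + sum(null_d <= d_obs)) / (n_perm + 1)
  structure(
    list(discrepancy = d_obs, score = 1 - d_obs / total, p_value = p,
         degenerate = degenerate, n_perm = n_perm, null_discrepancy = null_d),
    class = "nestedness_test"
  )
}

#' @export
print.nestedness_test <- function(x, ...) {
  cat("Checkerboard-swap nestedness test\n")
  cat("  discrepancy d =", x$discrepancy,
      " score =", round(x$score, 3),
      " p =", format.pval(x$p_value, digits = 3), "\n")
  if (x$degenerate) cat("  (degenerate null: no swappable checkerboards)\n")
  invisible(x)
}

#' @export
#' @method tidy nestedness_test
tidy.nestedness_test <- function(x, ...) {
  tibble::tibble(
    discrepancy = x$discrepancy, score = x$score, p_value = x$p_value,
    degenerate = x$degenerate, n_perm = x$n_perm
  )
}
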