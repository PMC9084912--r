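#' Total CPM Hamiltonian of a lattice configuration
#'
#' Computes the energy of a configuration as the sum of contact (surface)
#' energies over all unordered Moore neighbor pairs with unlike owners, plus
#' the elastic area penalty \eqn{\lambda_V (v(\sigma) - V_\tau)^2} summed over
#' cells. Each neighbor pair is counted once. The lattice is periodic.
#'
#' @param owner integer matrix of cell identifiers (0 = medium), indexed
#'   `owner[x + 1, y + 1]` for site (x, y).
#' @param cell_type integer vector, type of cell id 1..n (types are 1-based;
#'   medium is type 0).
#' @param J symmetric contact-energy matrix indexed by type + 1, so `J[1, 1]`
#'   is medium-medium (conventionally 0), `J[1, 2]` medium-type 1, etc.
#' @param lambda_v,target_area per-cell elastic constants and target areas.
#' @return total energy (scalar).
#' @export
hamiltonian_total <- function(owner, cell_type, J, lambda_v, target_area) {
  n_cells <- length(cell_type)
  ids <- unique(as.vector(owner))
  if (any(ids < 0) || any(ids > n_cells)) {
    stop("unknown cell id on lattice")
  }
  if (!isTRUE(all.equal(J, t(J)))) stop("contact energy table must be symmetric")
  type_of <- c(0L, as.integer(cell_type)) # index by owner + 1
  tmat <- matrix(type_of[owner + 1L], nrow(owner), ncol(owner))
  # count each unordered Moore pair once via 4 unique offsets
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  shift <- function(m, dx, dy) {
    W <- nrow(m); H <- ncol(m)
    m[(seq_len(W) - 1L + dx) %% W + 1L, (seq_len(H) - 1L + dy) %% H + 1L,
      drop = FALSE]
  }
  e_adh <- 0
  for (o in offsets) {
    ow2 <- shift(owner, o[1], o[2])
    tm2 <- shift(tmat, o[1], o[2])
    unlike <- owner != ow2
    if (any(unlike)) {
      e_adh <- e_adh + sum(J[cbind(tmat[unlike] + 1L, tm2[unlike] + 1L)])
    }
  }
  areas <- tabulate(owner[owner > 0L], nbins = n_cells)
  e_area <- sum(lambda_v * (areas - target_area)^2)
  e_adh + e_area
}

#' Incremental base-Hamiltonian change for one copy attempt
#'
#' Energy difference (adhesion + area terms only) if site (x, y) adopts the
#' owner of its Moore neighbor (xn, yn). Matches a full-Hamiltonian
#' recomputation but costs only a local neighborhood scan; this is the code
#' path the Metropolis kernel uses.
#'
#' @inheritParams hamiltonian_total
#' @param x,y target site (0-based), the site whose identity would change.
#' @param xn,yn source site (0-based), a Moore neighbor of (x, y).
#' @return energy difference.
#' @export
delta_h_base <- function(owner, cell_type, J, lambda_v, target_area,
                         x, y, xn, yn) {
  delta_h_base_cpp(owner, as.integer(cell_type), J, lambda_v, target_area,
                   x, y, xn, yn)
}

#' Metropolis acceptance probability
#'
#' Probability of accepting a copy attempt with energy change `dh` at
#' temperature `T`: 1 for non-positive `dh`, `exp(-dh / T)` otherwise.
#' An infinite `dh` (blocked attempt) yields 0.
#'
#' @param dh energy change (vectorized).
#' @param temperature simulation temperature, must be > 0.
#' @return probabilities in \[0, 1\].
#' @export
acceptance_probability <- function(dh, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  ifelse(dh <= 0, 1, exp(-dh / temperature))
}

#' Local connectivity test for a copy attempt
#'
#' Tests whether the sites of the cell owning (x, y) that lie in the Moore
#' neighborhood of (x, y) remain a single Moore-connected component after
#' site (x, y) is removed (the standard local test used to enforce the
#' connectivity constraint). Removal of a cell's last site is allowed.
#'
#' @inheritParams delta_h_base
#' @return TRUE when the removal keeps the local neighborhood connected.
#' @export
local_connectivity_ok <- function(owner, x, y) {
  local_connectivity_cpp(owner, x, y)
}

#' Place cells as distinct random single pixels
#'
#' @param width,height lattice dimensions.
#' @param n_cells number of cells; must not exceed `width * height`.
#' @return integer `width x height` owner matrix with `n_cells` distinct
#'   single-site cells (ids 1..n_cells).
#' @export
initialize_random_cells <- function(width, height, n_cells) {
  if (n_cells > width * height) stop("cell count exceeds lattice capacity")
  owner <- matrix(0L, width, height)
  sites <- sample.int(width * height, n_cells)
  owner[sites] <- seq_len(n_cells)
  owner
}

# ---------------------------------------------------------------------------
# persistence extensions

#' Update the persistence target direction of a cell
#'
#' `t_new = (1 - dr) t_old + dr * dx / |dx|` with `dr = min(1 / decay_time, 1)`,
#' where `dx` is the centroid shift over the previous MCS. A zero shift leaves
#' the target direction unchanged (the continuous limit of the update).
#'
#' @param t_old current target direction, length-2 vector with norm <= 1.
#' @param dx centroid displacement over the last MCS.
#' @param decay_time decay time in MCS, >= 1.
#' @return updated target direction (norm <= 1 by convexity).
#' @export
update_target_direction <- function(t_old, dx, decay_time) {
  nrm <- sqrt(sum(dx^2))
  if (nrm == 0) return(t_old)
  dr <- min(1 / decay_time, 1)
  (1 - dr) * t_old + dr * dx / nrm
}

#' Basic-persistence energy change for a copy attempt
#'
#' \eqn{\sum_{\sigma \in S} -\lambda_P v(\sigma) (s \cdot t_\sigma)} over the
#' involved (non-medium) cells: copies aligned with a cell's target direction
#' are favored, weighted by cell area. Pass only the rows for the involved
#' cells; the medium contributes nothing.
#'
#' @param s update direction, unit vector from source toward target site.
#' @param target_dir matrix (one row per involved cell) of target directions.
#' @param areas areas of the involved cells.
#' @param lambda_p persistence strength (energy per site).
#' @return energy change.
#' @export
delta_h_persistence <- function(s, target_dir, areas, lambda_p) {
  if (length(areas) == 0) return(0)
  target_dir <- matrix(target_dir, ncol = 2)
  sum(-lambda_p * areas * (target_dir[, 1] * s[1] + target_dir[, 2] * s[2]))
}

#' Act geometric mean around a lattice site
#'
#' Geometric mean of the activity values over the Moore neighborhood of a
#' site (including the central site), restricted to sites sharing the central
#' site's cell identifier. A medium site, or any included site with activity
#' zero, gives 0.
#'
#' @inheritParams delta_h_base
#' @param activity numeric matrix of per-site activity values in
#'   \[0, max_act\].
#' @export
act_geometric_mean <- function(owner, activity, x, y) {
  act_gm_cpp(owner, activity, x, y)
}

#' Act-model energy change for a copy attempt
#'
#' \eqn{-(\lambda_{Act} / Max_{act}) (GM_{src} - GM_{tgt})}: a copy from a
#' high-activity context into a lower-activity one is favored, creating the
#' local positive feedback that yields persistent motion.
#'
#' @inheritParams act_geometric_mean
#' @param source,target 0-based (x, y) site coordinates of the extending
#'   (source) pixel and of the pixel whose identity would change (target).
#' @param lambda_act Act coupling strength; `max_act` the maximum activity.
#' @param max_act maximum activity value (MCS of memory).
#' @export
delta_h_act <- function(owner, activity, source, target, lambda_act, max_act) {
  gm_src <- act_gm_cpp(owner, activity, source[1], source[2])
  gm_tgt <- act_gm_cpp(owner, activity, target[1], target[2])
  -(lambda_act / max_act) * (gm_src - gm_tgt)
}

#' Decay an Act activity field by one MCS
#'
#' Every positive activity value is decremented by one, with floor zero;
#' activity outside cells is zero.
#'
#' @inheritParams act_geometric_mean
#' @export
act_decay <- function(activity, owner = NULL) {
  out <- pmax(activity - 1, 0)
  if (!is.null(owner)) out[owner == 0L] <- 0
  out
}

# ---------------------------------------------------------------------------
# pseudopod extensions

#' Vector sum of a cell's pseudopods
#'
#' Sum over all non-empty pseudopods of the vector from the pseudopod origin
#' to its tip; a cell without pseudopods gives the zero vector.
#'
#' @param origins,tips matrices (one row per pseudopod) of origin and tip
#'   positions; may have zero rows.
#' @export
pseudopod_vector_sum <- function(origins, tips) {
  origins <- matrix(origins, ncol = 2)
  tips <- matrix(tips, ncol = 2)
  if (nrow(origins) == 0) return(c(0, 0))
  colSums(tips - origins)
}

#' Pseudopod pulling energy change for a copy attempt
#'
#' \eqn{\sum_{\sigma \in S} -F (s \cdot f_\sigma) / v(\sigma)} where
#' \eqn{f_\sigma} is the cell's pseudopod vector sum: copies aligned with the
#' combined pseudopod direction are favored, scaled down for large (heavy)
#' cells.
#'
#' @inheritParams delta_h_persistence
#' @param f matrix (one row per involved cell) of pseudopod vector sums.
#' @param pull_strength pulling force F.
#' @export
delta_h_pulling <- function(s, f, areas, pull_strength) {
  if (length(areas) == 0) return(0)
  f <- matrix(f, ncol = 2)
  sum(-pull_strength * (f[, 1] * s[1] + f[, 2] * s[2]) / areas)
}

#' Tip-adhesion energy change for one involved cell
#'
#' Case table on the minimum distances from the site changing identity to a
#' pseudopod tip of the involved cell (`r_self`) and of its nearest foreign
#' neighbor cell (`r_other`): no bonus when both exceed `r_max`, a single
#' bonus when exactly one is within range, a doubled bonus when both are.
#' For the cell shrinking in the attempt the bonus enters with opposite sign,
#' so a growth that displaces another cell nets zero ("no poking").
#'
#' @param r_self,r_other minimum tip distances (use `Inf` when a cell has no
#'   active pseudopod).
#' @param tip_bonus adhesion bonus energy E.
#' @param r_max maximum distance at which the bonus applies.
#' @param growing TRUE for the cell gaining the site, FALSE for the cell
#'   losing it.
#' @return signed energy contribution of this cell.
#' @export
delta_h_tip_adhesion <- function(r_self, r_other, tip_bonus, r_max,
                                 growing = TRUE) {
  b <- if (r_self <= r_max && r_other <= r_max) {
    -2 * tip_bonus
  } else if (r_self <= r_max || r_other <= r_max) {
    -tip_bonus
  } else {
    0
  }
  if (growing) b else -b
}

#' Apply a touch behavior to a pseudopod that hit a neighboring cell
#'
#' When actin growth is attempted into a site owned by another cell the
#' growth is rejected and the pseudopod is "touching"; what happens next
#' depends on the configured behavior: `nothing` leaves the state unchanged,
#' `retract` switches to RETRACTING, `attach` switches to TOUCHING (from
#' which retraction starts each MCS with probability `p_touch_retr`), and
#' `poof-dir` instantly removes lateral pseudopods (those whose origin-to-tip
#' direction has cosine below `lateral_threshold` with the cell's movement
#' direction) and restarts them at INIT — a Contact Inhibition of Locomotion
#' rule.
#'
#' @param state current FSM state, one of `"GROWING"`, `"TOUCHING"`.
#' @param behavior one of `"nothing"`, `"retract"`, `"attach"`, `"poof-dir"`.
#' @param pod_vector origin-to-tip vector of the pseudopod.
#' @param move_dir the cell's current (smoothed) movement direction.
#' @param lateral_threshold cosine threshold for `poof-dir` (default 0.85).
#' @return new FSM state (a string; `"INIT"` implies the chain was cleared).
#' @export
handle_touch <- function(state, behavior, pod_vector = c(0, 0),
                         move_dir = c(0, 0), lateral_threshold = 0.85) {
  switch(behavior,
    "nothing" = state,
    "retract" = "RETRACTING",
    "attach" = "TOUCHING",
    "poof-dir" = {
      pn <- sqrt(sum(pod_vector^2))
      mn <- sqrt(sum(move_dir^2))
      if (pn < 1e-12 || mn < 1e-12) return(state)
      cos_a <- sum(pod_vector * move_dir) / (pn * mn)
      if (cos_a < lateral_threshold) "INIT" else state
    },
    stop("unknown touch behavior: ", behavior)
  )
}

#' Draw directions from a von Mises distribution
#'
#' Angles (radians) from a von Mises distribution with the given mean
#' direction and concentration; `kappa = 0` reduces to the uniform circular
#' distribution. Sampling uses the Best-Fisher rejection scheme and R's RNG.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration, >= 0.
#' @return angles in (-pi, pi\].
#' @export
sample_von_mises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be non-negative")
  rvonmises_cpp(n, mu, kappa)
}
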