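# Shared helpers: random lattice configurations, independent (brute-force)
# oracles, and a Moore-connected-component labeller.

# random owner configuration with n_cells ids scattered over a W x H lattice
random_configuration <- function(W, H, n_cells, p_medium = 0.4) {
  owner <- matrix(sample(0:n_cells, W * H, replace = TRUE,
                         prob = c(p_medium, rep((1 - p_medium) / n_cells,
                                                n_cells))),
                  W, H)
  J <- matrix(runif(4, 1, 10), 2, 2)
  J <- (J + t(J)) / 2
  J[1, 1] <- 0
  list(owner = owner, cell_type = rep(1L, n_cells), J = J,
       lambda_v = runif(n_cells, 0.5, 2),
       target_area = sample(5:50, n_cells, replace = TRUE))
}

# draw a copy attempt (target site + Moore-neighbor source with a different
# owner); returns NULL when the random pick is a same-owner pair
random_attempt <- function(owner) {
  W <- nrow(owner); H <- ncol(owner)
  x <- sample(0:(W - 1), 1); y <- sample(0:(H - 1), 1)
  nb <- expand.grid(dx = -1:1, dy = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
  k <- sample(8, 1)
  xn <- (x + nb$dx[k]) %% W
  yn <- (y + nb$dy[k]) %% H
  if (owner[x + 1, y + 1] == owner[xn + 1, yn + 1]) return(NULL)
  list(x = x, y = y, xn = xn, yn = yn)
}

# apply a copy attempt to an owner matrix
apply_attempt <- function(owner, at) {
  owner[at$x + 1, at$y + 1] <- owner[at$xn + 1, at$yn + 1]
  owner
}

# independent R-native geometric mean for the Act field (Moore neighborhood
# incl. center, restricted to the central site's owner; medium -> 0)
gm_oracle <- function(owner, activity, x, y) {
  W <- nrow(owner); H <- ncol(owner)
  own <- owner[x + 1, y + 1]
  if (own == 0) return(0)
  vals <- c()
  for (dx in -1:1) for (dy in -1:1) {
    xi <- (x + dx) %% W; yi <- (y + dy) %% H
    if (owner[xi + 1, yi + 1] == own) {
      vals <- c(vals, activity[xi + 1, yi + 1])
    }
  }
  exp(mean(log(vals)))
}

# Moore-connected components of one cell's sites on a periodic lattice;
# returns the number of components
n_components <- function(owner, id) {
  W <- nrow(owner); H <- ncol(owner)
  sites <- which(owner == id)
  if (length(sites) == 0) return(0L)
  idx <- setNames(seq_along(sites), sites)
  visited <- rep(FALSE, length(sites))
  comps <- 0L
  for (s in seq_along(sites)) {
    if (visited[s]) next
    comps <- comps + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      lin <- sites[cur] - 1
      x <- lin %% W; y <- lin %/% W
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nlin <- ((x + dx) %% W) + ((y + dy) %% H) * W
        j <- idx[as.character(nlin + 1)]
        if (!is.na(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  comps
}

# brute-force uncorrected Ripley K (no edge correction)
k_naive <- function(points, area, r) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  diag(d) <- Inf
  vapply(r, function(ri) area * sum(d <= ri) / (n * (n - 1)), numeric(1))
}

# small straight-line track set
straight_tracks <- function(n = 3, steps = 10, dt = 1) {
  as_tracks(do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(track_id = i, t = (0:steps) * dt,
               x = (0:steps) * i, y = (0:steps) * 0.5 * i)
  })), dt = dt)
}
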