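#' Vessel network for tumor-induced angiogenesis
#'
#' Endothelial-cell (EC) occupancy plus the sprout tips whose stochastic
#' migration extends the network.  A parent vessel spans one column near the
#' left boundary; each initial tip starts its own sprout.  Chemotaxis toward
#' VEGF (coefficient `alpha`, saturation `kv`) and haptotaxis up fibronectin
#' gradients (coefficient `lambda`) drive tip migration.
#'
#' @param L lattice size.
#' @param parent_col column index of the parent vessel.
#' @param tip_rows row (j) positions of the initial sprout tips; tips are
#'   placed one site to the right of the parent vessel so each sprout starts
#'   4-connected to it.
#' @param hour clock hour at creation (sprout birth time).
#' @param alpha chemotactic coefficient.
#' @param kv chemotactic saturation constant (> 0).
#' @param lambda haptotactic coefficient.
#' @return object of class `vessel_network`.
#' @export
new_vessel_network <- function(L, parent_col = 3L, tip_rows, hour = 0,
                               alpha = 1, kv = 1, lambda = 0.3) {
  stopifnot(kv > 0, all(tip_rows >= 1), all(tip_rows <= L),
            parent_col >= 1, parent_col < L)
  ec <- matrix(0L, L, L)
  ec_sprout <- matrix(0L, L, L)
  ec[parent_col, ] <- 1L
  tips <- data.frame(tip_id = integer(0), i = integer(0), j = integer(0),
                     sprout = integer(0))
  sprouts <- data.frame(id = integer(0), birth = numeric(0),
                        merged_into = integer(0))
  edges <- data.frame(from_i = integer(0), from_j = integer(0),
                      to_i = integer(0), to_j = integer(0),
                      sprout = integer(0), hour = numeric(0))
  net <- structure(list(L = L, ec = ec, ec_sprout = ec_sprout,
                        parent_col = parent_col, tips = tips,
                        sprouts = sprouts, edges = edges,
                        alpha = alpha, kv = kv, lambda = lambda,
                        n_blocked = 0L, n_merged = 0L, next_tip_id = 1L),
                   class = "vessel_network")
  for (r in as.integer(tip_rows)) {
    sid <- nrow(net$sprouts) + 1L
    net$sprouts[sid, ] <- list(sid, hour, 0L)
    ti <- parent_col + 1L
    net$ec[ti, r] <- 1L
    net$ec_sprout[ti, r] <- sid
    net$tips <- rbind(net$tips,
                      data.frame(tip_id = net$next_tip_id, i = ti, j = r,
                                 sprout = sid))
    net$next_tip_id <- net$next_tip_id + 1L
    net$edges <- rbind(net$edges,
                       data.frame(from_i = parent_col, from_j = r,
                                  to_i = ti, to_j = r, sprout = sid,
                                  hour = hour))
  }
  net
}

# grid lookup with zero-flux (cell-centered Neumann) out-of-range indices:
# the ghost equals the edge cell, so boundary-normal gradients vanish
mirror_at <- function(g, i, j) {
  L1 <- nrow(g); L2 <- ncol(g)
  if (i < 1) i <- 1L else if (i > L1) i <- L1
  if (j < 1) j <- 1L else if (j > L2) j <- L2
  g[i, j]
}

#' Tip-cell migration distribution
#'
#' Un-normalized direction weights for a tip at `(i, j)`:
#' \deqn{P_k = \frac{\alpha k_v}{k_v + V_{ij}} (V_k - V_{ij}) +
#'             \lambda (F_k - F_{ij})}
#' for k = up (j+1), down (j-1), right (i+1), left (i-1); negative weights
#' (down-gradient directions) are clamped to zero, the stay weight `P5` is
#' the mean of the four clamped direction weights, and the five weights are
#' normalized to a probability vector.  An all-zero raw vector degenerates
#' to "stay with probability 1".
#'
#' @param tip integer `c(i, j)` position.
#' @param vegf,fibronectin VEGF and fibronectin grids (matrices or
#'   [make_field()] objects).
#' @param params list with `alpha`, `kv`, `lambda` (a `vessel_network` works).
#' @return object of class `migration_distribution`: `p_raw` (clamped,
#'   length 5), `p_norm` (sums to 1), `breaks` (right ends of the intervals
#'   I1..I5 partitioning (0, 1]).
#' @export
tip_migration_distribution <- function(tip, vegf, fibronectin, params) {
  V <- if (inherits(vegf, "field")) vegf$grid else vegf
  Fg <- if (inherits(fibronectin, "field")) fibronectin$grid else fibronectin
  i <- tip[1]; j <- tip[2]
  v0 <- V[i, j]; f0 <- Fg[i, j]
  coef <- params$alpha * params$kv / (params$kv + v0)
  dirs <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))  # up,down,right,left
  p <- vapply(dirs, function(d) {
    coef * (mirror_at(V, i + d[1], j + d[2]) - v0) +
      params$lambda * (mirror_at(Fg, i + d[1], j + d[2]) - f0)
  }, numeric(1))
  p <- pmax(p, 0)
  p5 <- mean(p)
  p_raw <- c(p, p5)
  tot <- sum(p_raw)
  p_norm <- if (tot > 0) p_raw / tot else c(0, 0, 0, 0, 1)
  structure(list(p_raw = p_raw, p_norm = p_norm, breaks = cumsum(p_norm)),
            class = "migration_distribution")
}

# interval index of a uniform draw r in the partition (0,1]: smallest k with
# r <= breaks[k] and interval of positive length
interval_of <- function(dist, r) {
  lo <- c(0, dist$breaks[-5])
  for (k in 1:5) if (r > lo[k] && r <= dist$breaks[k]) return(k)
  5L
}

# place/move a tip onto (ti, tj); handles EC-occupancy as anastomosis.
# Returns updated net; `moved` attribute FALSE when blocked by tumor.
advance_tip <- function(net, tip_idx, ti, tj, x_tum, hour) {
  L <- net$L
  if (ti < 1 || ti > L || tj < 1 || tj > L) {
    net$n_blocked <- net$n_blocked + 1L
    return(net)
  }
  if (x_tum[ti, tj] == 1L) {                 # blocked by a tumor cell
    net$n_blocked <- net$n_blocked + 1L
    return(net)
  }
  from <- c(net$tips$i[tip_idx], net$tips$j[tip_idx])
  sid <- net$tips$sprout[tip_idx]
  if (net$ec[ti, tj] == 1L) {                # anastomosis: fuse with vessel
    other <- net$ec_sprout[ti, tj]
    net <- merge_sprouts(net, sid, other)
    sid <- net$tips$sprout[tip_idx] <- min_id(net, sid, other)
    net$tips$i[tip_idx] <- ti; net$tips$j[tip_idx] <- tj
  } else {
    net$ec[ti, tj] <- 1L
    net$ec_sprout[ti, tj] <- sid
    net$tips$i[tip_idx] <- ti; net$tips$j[tip_idx] <- tj
  }
  net$edges <- rbind(net$edges,
                     data.frame(from_i = from[1], from_j = from[2],
                                to_i = ti, to_j = tj, sprout = sid,
                                hour = hour))
  net
}

min_id <- function(net, a, b) {
  if (b == 0L) return(a)   # parent vessel carries sprout id 0: keep own id
  min(a, b)
}

merge_sprouts <- function(net, a, b) {
  if (b == 0L || a == b) return(net)         # meeting the parent vessel
  keep <- min(a, b); drop <- max(a, b)
  net$tips$sprout[net$tips$sprout == drop] <- keep
  net$ec_sprout[net$ec_sprout == drop] <- keep
  net$sprouts$merged_into[net$sprouts$id == drop] <- keep
  net$n_merged <- net$n_merged + 1L
  net
}

sprout_birth <- function(net, sid) {
  net$sprouts$birth[match(sid, net$sprouts$id)]
}

#' Branch or migrate one sprout tip
#'
#' Implements the stated per-tip stochastic update.  Branching happens iff
#' the sprout is strictly older than 18 h, a free nearest-neighbor site
#' exists, and two uniform draws satisfy `r1 in I2` and `r2 in I3`; the tip
#' then emits two daughter ECs, one below (j-1) and one to the right (i+1),
#' each starting a fresh sprout (ages reset), and retires.  Otherwise one
#' draw `r` decides migration.  In the default `"literal"` mode the tip moves
#' right iff `r in I3` (the rule as printed); in `"generalized"` mode the
#' direction up/down/right/left/stay is the interval `r` falls in.  Moves
#' blocked by tumor cells are skipped (counted in `n_blocked`); moves onto
#' existing ECs fuse the sprouts (anastomosis).
#'
#' @param net a [new_vessel_network()].
#' @param tip_idx row index into `net$tips`.
#' @param dist a [tip_migration_distribution()].
#' @param x_tum tumor occupancy mask (ECs cannot enter tumor sites).
#' @param hour current clock hour (for sprout ages and edge stamps).
#' @param mode `"literal"` or `"generalized"`.
#' @param draws optional named list of fixed uniforms (`r1`, `r2`, `r`) for
#'   deterministic testing; drawn from the RNG stream when `NULL`.
#' @return updated network.
#' @export
branch_or_migrate <- function(net, tip_idx, dist, x_tum, hour,
                              mode = c("literal", "generalized"),
                              draws = NULL) {
  mode <- match.arg(mode)
  i <- net$tips$i[tip_idx]; j <- net$tips$j[tip_idx]
  sid <- net$tips$sprout[tip_idx]
  age_ok <- (hour - sprout_birth(net, sid)) > 18
  nb <- lattice_neighbors(i, j, net$L, type = "vonneumann")
  free <- nb[net$ec[nb] == 0L & x_tum[nb] == 0L, , drop = FALSE]
  if (age_ok && nrow(free) > 0) {
    r1 <- if (is.null(draws)) runif(1) else draws$r1
    r2 <- if (is.null(draws)) runif(1) else draws$r2
    if (interval_of(dist, r1) == 2L && interval_of(dist, r2) == 3L) {
      # branch: daughters below and right, fresh sprouts, parent tip retires
      net$tips <- net$tips[-tip_idx, , drop = FALSE]
      for (d in list(c(0L, -1L), c(1L, 0L))) {
        nsid <- nrow(net$sprouts) + 1L
        net$sprouts[nsid, ] <- list(nsid, hour, 0L)
        net$tips <- rbind(net$tips,
                          data.frame(tip_id = net$next_tip_id, i = i, j = j,
                                     sprout = nsid))
        net$next_tip_id <- net$next_tip_id + 1L
        net <- advance_tip(net, nrow(net$tips), i + d[1], j + d[2],
                           x_tum, hour)
        # daughter blocked on the spot: drop the stillborn tip
        if (net$tips$i[nrow(net$tips)] == i && net$tips$j[nrow(net$tips)] == j)
          net$tips <- net$tips[-nrow(net$tips), , drop = FALSE]
      }
      return(net)
    }
  }
  r <- if (is.null(draws)) runif(1) else draws$r
  k <- interval_of(dist, r)
  if (mode == "literal") {
    if (k == 3L) net <- advance_tip(net, tip_idx, i + 1L, j, x_tum, hour)
    return(net)
  }
  step <- switch(k, c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L), NULL)
  if (!is.null(step))
    net <- advance_tip(net, tip_idx, i + step[1], j + step[2], x_tum, hour)
  net
}

#' Resolve tip collisions (anastomosis pass)
#'
#' When two tips end a step on the same lattice site their sprouts fuse and
#' exactly one tip survives.
#'
#' @param net a [new_vessel_network()].
#' @return updated network.
#' @export
anastomosis <- function(net) {
  if (nrow(net$tips) < 2) return(net)
  key <- paste(net$tips$i, net$tips$j)
  dup <- duplicated(key)
  if (!any(dup)) return(net)
  for (k in unique(key[dup])) {
    idx <- which(key == k)
    ids <- net$tips$sprout[idx]
    keep <- min(ids)
    for (other in setdiff(ids, keep)) net <- merge_sprouts(net, keep, other)
    net$tips$sprout[idx] <- keep
  }
  key <- paste(net$tips$i, net$tips$j)
  net$tips <- net$tips[!duplicated(key), , drop = FALSE]
  net
}

#' Endothelial-cell count
#' @param net a [new_vessel_network()].
#' @return number of EC-occupied sites.
#' @export
ec_count <- function(net) sum(net$ec)
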