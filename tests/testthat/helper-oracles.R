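# Independent oracles used by the test suite. These deliberately use
# different algorithms from the package implementation.

# --- extrema / feature oracle -------------------------------------------------
# Sublevel-set flooding (union-find persistence) on a circular profile:
# sweep values from low to high; a new connected component is born at each
# local minimum, and when two components meet at a maximum the younger one
# (shallower basin) dies with persistence = merge level - birth level.
# Surviving minima are those whose persistence >= prominence (the global
# minimum survives always). Maxima surviving are derived by the complementary
# sweep from high to low.
oracle_clear_minima <- function(v, prominence) {
  n <- length(v)
  ord <- order(v, seq_len(n))   # deterministic tie-break by index
  comp <- rep(NA_integer_, n)   # component id per grid point
  birth <- numeric(0)           # birth level per component id
  root <- integer(0)            # representative minimum index per component
  parent <- integer(0)          # union-find
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  alive <- c()
  killed <- list()
  for (p in ord) {
    left <- (p - 2) %% n + 1
    right <- p %% n + 1
    nb <- c(left, right)
    nb <- nb[!is.na(comp[nb])]
    nb_roots <- unique(vapply(nb, function(q) find(comp[q]), integer(1)))
    if (length(nb_roots) == 0L) {
      id <- length(parent) + 1L
      parent[id] <- id
      birth[id] <- v[p]
      root[id] <- p
      comp[p] <- id
    } else if (length(nb_roots) == 1L) {
      comp[p] <- nb_roots
    } else {
      # merge: older (lower birth) survives; ties broken by lower root index
      o <- nb_roots[order(birth[nb_roots], root[nb_roots])]
      survivor <- o[1]
      for (dying in o[-1]) {
        killed[[length(killed) + 1L]] <-
          list(min_idx = root[dying], persistence = v[p] - birth[dying])
        parent[dying] <- survivor
      }
      comp[p] <- survivor
    }
  }
  ids <- which(parent == seq_along(parent))
  survivors <- root[ids]   # never-merged components (incl. global minimum)
  for (k in killed) {
    if (k$persistence >= prominence) survivors <- c(survivors, k$min_idx)
  }
  sort(survivors)
}

# Full feature oracle: clear minima via sublevel flooding; clear maxima via
# the same flooding applied to the negated profile; features by definition.
# The global-minimum/global-maximum pair has persistence equal to the profile
# range, so a profile whose range falls below the prominence threshold is
# featureless (one minimum, no clear maximum).
oracle_features <- function(v, prominence) {
  if (max(v) - min(v) < prominence) {
    return(list(n_minima = 1L, ddVmin = 0, maxVmax = 0, minVmax = 0,
                minima = which.min(v), maxima = integer(0)))
  }
  mins <- oracle_clear_minima(v, prominence)
  maxs <- oracle_clear_minima(-v, prominence)
  rel <- v - min(v)
  list(n_minima = length(mins),
       ddVmin = max(rel[mins]) - min(rel[mins]),
       maxVmax = max(rel[maxs]),
       minVmax = min(rel[maxs]),
       minima = mins, maxima = maxs)
}

# Random smooth periodic profiles in "generic position" (distinct extremum
# levels, no plateaus): low-order random Fourier series on the 36-point grid.
random_profile <- function(n = 36, order_max = 4) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  v <- rep(0, n)
  for (m in seq_len(order_max)) {
    v <- v + stats::rnorm(1, 0, 4 / m) * cos(m * th) +
      stats::rnorm(1, 0, 4 / m) * sin(m * th)
  }
  v - min(v)
}

# --- geometry oracle ----------------------------------------------------------
# Explicit Rodrigues rotation of a point set about the axis through p0 with
# direction u (unit), by angle theta (radians).
oracle_rotate <- function(pts, p0, u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  t(Rm %*% (t(pts) - p0) + p0)
}

# --- fragmentation oracle -----------------------------------------------------
# Breadth-first shell expansion on the heavy-atom adjacency list, followed by
# exhaustive ring-closure: any heavy atom lying on a cycle through an included
# atom is included (cycle membership via bond-is-not-a-bridge on the full
# graph, iterated to a fixed point), plus multiple-bond partners.
oracle_fragment_atoms <- function(mol, i, j, shells) {
  n <- nrow(mol$atoms)
  heavy <- mol$atoms$element != "H"
  adj <- lapply(seq_len(n), function(k) integer(0))
  for (r in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$i[r]; b <- mol$bonds$j[r]
    if (heavy[a] && heavy[b]) {
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  frontier <- c(i, j); included <- rep(FALSE, n); included[frontier] <- TRUE
  for (s in seq_len(shells)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!included[nxt]]
    included[nxt] <- TRUE
    frontier <- nxt
  }
  ring_bonds <- mol$bonds[mol$bonds$in_ring, , drop = FALSE]
  repeat {
    before <- sum(included)
    for (r in seq_len(nrow(ring_bonds))) {
      a <- ring_bonds$i[r]; b <- ring_bonds$j[r]
      if (included[a] || included[b]) included[c(a, b)] <- TRUE
    }
    for (r in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$i[r]; b <- mol$bonds$j[r]
      if (mol$bonds$order[r] > 1L && (included[a] || included[b])) {
        included[c(a, b)] <- TRUE
      }
    }
    if (sum(included) == before) break
  }
  sort(which(included & heavy))
}
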