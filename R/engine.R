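# Internal simulation engines for the two-state chain.
#
# State is a logical vector over units (TRUE = sensitive). At each step a
# single uniform draw per unit serves both transitions: a sensitive unit
# releases (spikes) if u < p_b(t) and becomes insensitive; an insensitive
# unit regenerates if u < p_c. At most one spike per unit per step, and
# never while insensitive.

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Release-probability template for one sweep segment.
.pb_values <- function(params, grid, stim_values, k2 = params$k2) {
  .clip01((params$k1 * stim_values + k2 * params$s0) * grid$lambda_star)
}

# Run n_units independent chains for n_sweeps repetitions of a per-step
# probability template `pb` (state carries over between sweeps). Returns a
# data frame with columns unit, sweep, step (1-based within sweep).
.run_template <- function(pb, pc, n_sweeps, n_units, init_sensitive = TRUE) {
  L <- length(pb)
  state <- rep(isTRUE(init_sensitive), n_units)
  hits <- vector("list", n_sweeps * L)
  k <- 0L
  for (sw in seq_len(n_sweeps)) {
    for (t in seq_len(L)) {
      k <- k + 1L
      u <- runif(n_units)
      sp <- state & (u < pb[t])
      state <- (state & !sp) | (!state & (u < pc))
      hits[[k]] <- which(sp)
    }
  }
  ns <- lengths(hits)
  idx <- which(ns > 0L)
  total <- rep.int(seq_len(n_sweeps * L), ns)
  list(
    unit = unlist(hits, use.names = FALSE) %||% integer(),
    sweep = (total - 1L) %/% L + 1L,
    step = (total - 1L) %% L + 1L
  )
}

# Heterogeneous-unit engine: pb_step(t) returns the per-unit release
# probability vector at step t; pc is per-unit. Initial state may be a
# logical vector. Returns list(step, unit).
.run_matrix <- function(n_steps, n_units, pb_step, pc, init_state) {
  state <- rep_len(init_state, n_units)
  hits <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    u <- runif(n_units)
    sp <- state & (u < pb_step(t))
    state <- (state & !sp) | (!state & (u < pc))
    hits[[t]] <- which(sp)
  }
  ns <- lengths(hits)
  list(
    step = rep.int(seq_len(n_steps), ns),
    unit = unlist(hits, use.names = FALSE) %||% integer()
  )
}

# Exact occupancy propagation over one periodic sweep template.
# Returns the steady-state occupancy at sweep start (p0), the per-step
# occupancy p (probability sensitive just before each step's transition)
# and per-step expected spikes e = p * pb.
.expected_sweep <- function(pb, pc) {
  r <- 1 - pb - pc
  a <- prod(r)
  # b: constant term of the affine sweep map p_end = a * p0 + b
  suffix <- rev(cumprod(rev(r)))            # prod_{j >= t} r_j
  suffix <- c(suffix[-1], 1)                # prod_{j > t} r_j
  b <- pc * sum(suffix)
  p0 <- if (abs(1 - a) < 1e-15) 1 else b / (1 - a)
  L <- length(pb)
  p <- numeric(L)
  pt <- p0
  for (t in seq_len(L)) {
    p[t] <- pt
    pt <- pt * r[t] + pc
  }
  list(p0 = p0, p = p, e = p * pb)
}

# Closed-form expected spontaneous spike count over the active half of the
# periodic session (active half: constant pb_a; re-equilibration half:
# constant pb_r), at steady state.
.spont_count_session <- function(pb_a, pb_r, pc, n_active, n_requil) {
  phase <- function(pb, n, p0) {
    # p_t = p* + (p0 - p*) r^t ; returns end occupancy and sum of p over n steps
    r <- 1 - pb - pc
    pstar <- if (pb + pc > 0) pc / (pb + pc) else 1
    if (abs(1 - r) < 1e-15) {
      list(end = p0, sum = n * p0)
    } else {
      list(
        end = pstar + (p0 - pstar) * r^n,
        sum = n * pstar + (p0 - pstar) * (1 - r^n) / (1 - r)
      )
    }
  }
  # steady-state p0 solves p0 = g_requil(g_active(p0)), both affine
  f <- function(p0) phase(pb_r, n_requil, phase(pb_a, n_active, p0)$end)$end
  a <- f(1) - f(0)
  b <- f(0)
  p0 <- if (abs(1 - a) < 1e-15) 1 else b / (1 - a)
  pb_a * phase(pb_a, n_active, p0)$sum
}
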