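# Lightweight private RNG streams so that thermal noise and crosslink
# kinetics draw from independent, individually reproducible sequences.
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- withr::with_seed(as.integer(seed), get(".Random.seed",
                                                    envir = globalenv()))
  e
}

with_stream <- function(stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Bead-spring polymer parameters
#'
#' Parameters of the budding-yeast genome model: a bead chain (about 5 kb of
#' DNA per bead; 2803 beads by default, of which a contiguous block of 361
#' is the rDNA locus) confined to a spherical nucleus, with the centromeric
#' bead tethered to a point on the nuclear envelope. rDNA beads form
#' transient pairwise crosslinks (mimicking a limited pool of
#' condensin/cohesin linkers): each rDNA bead with spare link capacity
#' attempts crosslink formation at rate `k_on` (probability
#' `1 - exp(-k_on * dt)` per step) and, on an attempt, links to a
#' uniformly random eligible partner within `capture_radius`; each link
#' lives for an exponential time with mean `mu` seconds. Linker-limited
#' (per-bead) attempt kinetics make the steady-state link occupancy a
#' saturating, monotone function of `mu` that is insensitive to local
#' bead density.
#'
#' Dynamics are overdamped Langevin: Hookean springs between chain
#' neighbours (and across active crosslinks), a thermal kick of per-axis
#' variance `2 * kT * dt / drag`, and hard projection back to the
#' confinement sphere. Units: nm, s, pN.
#'
#' @param n_beads total beads (default 2803).
#' @param n_rdna_beads rDNA beads, a contiguous block (default 361).
#' @param kb_per_bead kilobases represented per bead (bookkeeping only).
#' @param mu mean crosslink duration, seconds (study values 0.09/0.19/1.6).
#' @param k_on crosslink formation attempt rate per bead (1/s).
#' @param capture_radius pair distance (nm) below which links can form.
#' @param spring_constant Hookean stiffness (pN/nm) of chain and crosslink
#'   springs.
#' @param rest_length chain bond rest length (nm).
#' @param crosslink_rest rest length (nm) of crosslink springs.
#' @param crosslink_spring stiffness (pN/nm) of crosslink springs
#'   (default: same as `spring_constant`).
#' @param drag bead drag coefficient (pN s/nm).
#' @param kT thermal energy (pN nm).
#' @param dt time step (s); default keeps `dt * spring_constant / drag = 0.1`.
#' @param confinement_radius nuclear radius (nm).
#' @param tether_site 3-vector, attachment point on the nuclear envelope.
#' @param tether_beads indices of beads tethered to `tether_site` (empty
#'   vector for no tether).
#' @param max_links_per_bead maximum simultaneous crosslinks a bead can
#'   host (default 1, one condensin-style linker per bead; also keeps the
#'   per-bead spring stiffness bounded so the explicit integrator stays
#'   stable at the default `dt`).
#' @param ev_strength stiffness (pN/nm) of the soft excluded-volume
#'   repulsion between rDNA beads closer than `ev_range` (0 disables); a
#'   half-harmonic push that opposes crosslink-driven collapse.
#' @param ev_range excluded-volume interaction range (nm).
#' @param min_loop_sep minimum chain separation `|i - j|` for a
#'   crosslinkable rDNA pair (default 2; adjacent beads are already joined
#'   by chain springs, so only loop-forming contacts link).
#' @param form_every attempt crosslink formation only every this many
#'   update calls (default 5), with the per-attempt probability scaled to
#'   keep the formation rate `k_on`; link expiry is still checked every
#'   call. Formation involves all-pairs distance work, so this sets the
#'   cost/granularity trade-off (the default granularity, 10 ms at the
#'   default `dt`, is far below every studied `mu`).
#' @param init_seed if set, a fixed seed for the initial random-walk
#'   conformation, so every trajectory starts from the same reference
#'   configuration (global chain relaxation is far slower than any
#'   feasible simulation, so a shared start removes conformational
#'   variance that is frozen-in rather than sampled); `NULL` draws the
#'   initial conformation from the trajectory seed.
#' @param rdna_start first index of the rDNA block (default: centred).
#' @return an object of class `polymer_params`.
#' @export
polymer_params <- function(n_beads = 2803L, n_rdna_beads = 361L,
                           kb_per_bead = 5, mu = 0.19, k_on = 2,
                           capture_radius = 100, spring_constant = 0.05,
                           rest_length = 50, crosslink_rest = 0,
                           crosslink_spring = 0.1,
                           drag = 0.001, kT = 4.1, dt = 0.002,
                           confinement_radius = 1000,
                           tether_site = NULL, tether_beads = 1L,
                           max_links_per_bead = 1L, min_loop_sep = 2L,
                           ev_strength = 0.02, ev_range = 45,
                           form_every = 5L,
                           init_seed = NULL, rdna_start = NULL) {
  stopifnot_scalar_num(n_beads, "n_beads", min = 1)
  stopifnot_scalar_num(n_rdna_beads, "n_rdna_beads", min = 1)
  if (n_rdna_beads > n_beads) stop("n_rdna_beads must be <= n_beads")
  stopifnot_scalar_num(mu, "mu", min = 0, strict = TRUE)
  stopifnot_scalar_num(dt, "dt", min = 0, strict = TRUE)
  stopifnot_scalar_num(confinement_radius, "confinement_radius",
                       min = 0, strict = TRUE)
  stopifnot_scalar_num(k_on, "k_on", min = 0)
  if (rest_length >= 2 * confinement_radius)
    stop("rest_length must be < 2 * confinement_radius")
  if (is.null(tether_site)) tether_site <- c(0, 0, confinement_radius)
  if (is.null(rdna_start))
    rdna_start <- floor((n_beads - n_rdna_beads) / 2) + 1L
  if (rdna_start < 1L || rdna_start + n_rdna_beads - 1L > n_beads)
    stop("rDNA block does not fit in the chain")
  structure(list(
    n_beads = as.integer(n_beads), n_rdna_beads = as.integer(n_rdna_beads),
    kb_per_bead = kb_per_bead, mu = mu, k_on = k_on,
    capture_radius = capture_radius, spring_constant = spring_constant,
    rest_length = rest_length, crosslink_rest = crosslink_rest,
    crosslink_spring = if (is.null(crosslink_spring)) spring_constant
                       else crosslink_spring,
    drag = drag, kT = kT, dt = dt,
    confinement_radius = confinement_radius,
    tether_site = as.numeric(tether_site),
    tether_beads = as.integer(tether_beads),
    max_links_per_bead = as.integer(max_links_per_bead),
    min_loop_sep = as.integer(min_loop_sep),
    ev_strength = ev_strength, ev_range = ev_range,
    form_every = as.integer(form_every),
    init_seed = if (is.null(init_seed)) NULL else as.integer(init_seed),
    rdna_start = as.integer(rdna_start)
  ), class = "polymer_params")
}

#' rDNA-only polymer preset
#'
#' A reduced model simulating just the 361-bead rDNA block with both chain
#' ends tethered (standing in for the flanking chromosome-XII arms), used
#' for fast generation of crosslink-duration image classes. The preset
#' fixes the crosslink calibration (capture radius 150 nm, up to two
#' linkers per bead, a common reference starting conformation) at values
#' where the mean crosslink duration produces well-separated steady-state
#' compaction classes. All other parameters as [polymer_params()].
#'
#' @param mu mean crosslink duration (s).
#' @param n_rdna_beads block size (default 361).
#' @param ... passed to [polymer_params()].
#' @return an object of class `polymer_params`.
#' @export
rdna_only_params <- function(mu = 0.19, n_rdna_beads = 361L,
                             init_seed = 1702L, ...) {
  defaults <- list(n_beads = n_rdna_beads, n_rdna_beads = n_rdna_beads,
                   mu = mu, tether_beads = c(1L, as.integer(n_rdna_beads)),
                   rdna_start = 1L, init_seed = init_seed,
                   capture_radius = 150, max_links_per_bead = 2L)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(polymer_params, defaults)
}

#' Initialise the polymer chain
#'
#' Grows a random walk with step `rest_length`, rejecting steps that leave
#' the confinement sphere, starting from `tether_site` when a tether is
#' declared (so the centromeric bead sits at its attachment point).
#'
#' @param params a [polymer_params()] object.
#' @param seed integer seed.
#' @return an object of class `polymer_state`: bead positions, the active
#'   crosslink table, the simulation clock and a log of completed crosslink
#'   lifetimes.
#' @export
init_chain <- function(params, seed = 1L) {
  stopifnot(inherits(params, "polymer_params"))
  n <- params$n_beads
  R <- params$confinement_radius
  withr::with_seed(as.integer(seed), {
    pos <- matrix(0, n, 3L)
    pos[1L, ] <- if (length(params$tether_beads))
      params$tether_site * (1 - 1e-9) else {
        p <- rnorm(3); p / sqrt(sum(p^2)) * R * runif(1)^(1 / 3)
      }
    for (i in seq_len(n - 1L)) {
      repeat {
        d <- rnorm(3)
        cand <- pos[i, ] + d / sqrt(sum(d^2)) * params$rest_length
        if (sum(cand^2) <= R^2) break
      }
      pos[i + 1L, ] <- cand
    }
    structure(list(
      pos = pos,
      # active crosslinks: matrix with columns i, j, created, expiry
      links = matrix(numeric(), 0L, 4L,
                     dimnames = list(NULL, c("i", "j", "created", "expiry"))),
      time = 0,
      completed_lifetimes = numeric(),
      completed_created = numeric(),
      params = params,
      rdna_idx = seq.int(params$rdna_start,
                         length.out = params$n_rdna_beads)
    ), class = "polymer_state")
  })
}

# Verlet neighbour list over rDNA bead pairs, shared by the excluded-volume
# force and the crosslink capture test. Rebuilt when any rDNA bead has
# drifted more than half the list margin since the last build.
.vlist_margin <- 60
ensure_vlist <- function(state) {
  p <- state$params
  idx <- state$rdna_idx
  need_ev <- p$ev_strength > 0
  need_cl <- p$k_on > 0 && p$capture_radius > 0
  if (length(idx) < 2L || (!need_ev && !need_cl)) {
    if (is.null(state$vlist))
      state$vlist <- list(i = integer(), j = integer(), sep = integer())
    return(state)
  }
  vcut <- max(if (need_ev) p$ev_range else 0,
              if (need_cl) p$capture_radius else 0) + .vlist_margin
  rp <- state$pos[idx, , drop = FALSE]
  if (!is.null(state$vlist) &&
      max(abs(rp - state$vlist_pos)) < .vlist_margin / 2)
    return(state)
  pr <- state$pairs_all
  if (is.null(pr)) {
    nr <- length(idx)
    ut <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
    pr <- state$pairs_all <- list(iu = ut[, 1L], ju = ut[, 2L])
  }
  rs <- rowSums(rp * rp)
  G <- tcrossprod(rp)
  d2v <- rs[pr$iu] + rs[pr$ju] - 2 * G[cbind(pr$iu, pr$ju)]
  keep <- which(d2v < vcut^2)
  gi <- idx[pr$iu[keep]]; gj <- idx[pr$ju[keep]]
  state$vlist <- list(i = gi, j = gj, sep = abs(gj - gi))
  state$vlist_pos <- rp
  state
}

# Sum of spring/tether forces (pN) on every bead.
polymer_forces <- function(state) {
  p <- state$params
  pos <- state$pos
  n <- nrow(pos)
  F <- matrix(0, n, 3L)
  if (n > 1L)
    F <- F + spring_pair_forces_cpp(pos, seq_len(n - 1L), 2:n,
                                    p$spring_constant, p$rest_length, n)
  if (nrow(state$links))
    F <- F + spring_pair_forces_cpp(pos, as.integer(state$links[, 1L]),
                                    as.integer(state$links[, 2L]),
                                    p$crosslink_spring, p$crosslink_rest, n)
  if (p$ev_strength > 0 && length(state$vlist$i))
    F <- F + ev_pair_forces_cpp(pos, state$vlist$i, state$vlist$j,
                                p$ev_strength, p$ev_range, n)
  if (length(p$tether_beads)) {
    tb <- p$tether_beads
    d <- matrix(p$tether_site, length(tb), 3L, byrow = TRUE) -
      pos[tb, , drop = FALSE]
    F[tb, ] <- F[tb, , drop = FALSE] + p$spring_constant * d
  }
  F
}

#' One overdamped Langevin step
#'
#' Updates positions by `dt / drag` times the net spring force plus a
#' Gaussian thermal kick of per-axis variance `2 * kT * dt / drag`, then
#' projects any bead outside the confinement sphere back onto it.
#'
#' @param state a `polymer_state`.
#' @param thermal an RNG stream (internal) or `NULL` to use the current RNG.
#' @return the updated `polymer_state`.
#' @export
step_dynamics <- function(state, thermal = NULL) {
  state <- ensure_vlist(state)
  p <- state$params
  n <- nrow(state$pos)
  noise_sd <- sqrt(2 * p$kT * p$dt / p$drag)
  kick <- if (is.null(thermal)) {
    matrix(rnorm(3L * n, sd = noise_sd), n, 3L)
  } else {
    with_stream(thermal, matrix(rnorm(3L * n, sd = noise_sd), n, 3L))
  }
  pos <- state$pos + (p$dt / p$drag) * polymer_forces(state) + kick
  if (!all(is.finite(pos)))
    stop(sprintf("non-finite coordinates: integration unstable at dt = %g",
                 p$dt))
  r2 <- rowSums(pos^2)
  out <- r2 > p$confinement_radius^2
  if (any(out))
    pos[out, ] <- pos[out, , drop = FALSE] *
      (p$confinement_radius / sqrt(r2[out]))
  state$pos <- pos
  state$time <- state$time + p$dt
  state
}

#' Update transient rDNA crosslinks
#'
#' Removes links whose exponential lifetime has elapsed (logging the drawn
#' lifetime and creation time) and forms new links: every rDNA bead with
#' spare link capacity attempts formation with probability
#' `1 - exp(-k_on * dt)` and links to a uniformly random free partner
#' within `capture_radius` (at least `min_loop_sep` beads away along the
#' chain); each new link draws an `Exponential(mean = mu)` lifetime at
#' creation.
#'
#' @param state a `polymer_state`.
#' @param kinetics an RNG stream (internal) or `NULL` to use the current RNG.
#' @return the updated `polymer_state`.
#' @export
update_crosslinks <- function(state, kinetics = NULL) {
  p <- state$params
  run <- function(expr) if (is.null(kinetics)) expr else
    with_stream(kinetics, expr)
  links <- state$links
  expired <- links[, 4L] <= state$time
  if (any(expired)) {
    state$completed_lifetimes <- c(state$completed_lifetimes,
                                   links[expired, 4L] - links[expired, 3L])
    state$completed_created <- c(state$completed_created,
                                 links[expired, 3L])
    links <- links[!expired, , drop = FALSE]
  }
  state$tick <- (if (is.null(state$tick)) 0L else state$tick) + 1L
  if (p$k_on > 0 && p$capture_radius > 0 &&
      state$tick %% p$form_every == 0L) {
    state <- ensure_vlist(state)
    vl <- state$vlist
    cand <- which(vl$sep >= p$min_loop_sep)
    if (length(cand)) {
      gi <- vl$i[cand]; gj <- vl$j[cand]
      close <- which(pair_d2_cpp(state$pos, gi, gj) < p$capture_radius^2)
      gi <- gi[close]; gj <- gj[close]
    } else gi <- gj <- integer()
    if (length(gi)) {
      # bead occupancy: each bead hosts at most max_links_per_bead links
      occ <- integer(p$n_beads)
      if (nrow(links))
        occ <- tabulate(c(links[, 1L], links[, 2L]), p$n_beads)
      cap <- p$max_links_per_bead
      keep <- occ[gi] < cap & occ[gj] < cap
      if (nrow(links)) {
        key <- gi * (p$n_beads + 1) + gj
        taken <- links[, 1L] * (p$n_beads + 1) + links[, 2L]
        keep <- keep & !(key %in% taken)
      }
      gi <- gi[keep]; gj <- gj[keep]
      if (length(gi)) {
        ub <- unique(c(gi, gj))
        pform <- 1 - exp(-p$k_on * p$dt * p$form_every)
        run({
          att <- ub[runif(length(ub)) < pform]
          if (length(att) > 1L) att <- sample(att)
          for (b in att) {
            if (occ[b] >= cap) next
            mates <- c(gj[gi == b], gi[gj == b])
            mates <- mates[occ[mates] < cap]
            if (!length(mates)) next
            m <- if (length(mates) == 1L) mates else
              mates[sample.int(length(mates), 1L)]
            life <- rexp(1L, rate = 1 / p$mu)
            links <- rbind(links, c(min(b, m), max(b, m), state$time,
                                    state$time + life))
            occ[b] <- occ[b] + 1L
            occ[m] <- occ[m] + 1L
          }
        })
      }
    }
  }
  state$links <- links
  state
}

#' Run a polymer trajectory
#'
#' Burn-in, then `total_steps` further steps sampling a snapshot every
#' `sample_every` steps. Crosslink kinetics and thermal noise use
#' independent sub-streams derived from `seed`, so crosslink event
#' sequences are comparable across thermal realisations.
#'
#' @param params a [polymer_params()] object.
#' @param total_steps steps after burn-in.
#' @param sample_every snapshot interval in steps.
#' @param seed master seed.
#' @param burn_in equilibration steps (default 2000).
#' @return an object of class `polymer_trajectory`: full-chain snapshots,
#'   sample times, the rDNA index range, the completed-lifetime log and
#'   provenance (params + seed).
#' @export
run_trajectory <- function(params, total_steps, sample_every, seed = 1L,
                           burn_in = 2000L) {
  stopifnot(total_steps >= sample_every, sample_every >= 1)
  seeds <- derive_seeds(seed, 3L)
  state <- init_chain(params,
                      seed = if (is.null(params$init_seed)) seeds[1L]
                             else params$init_seed)
  thermal <- rng_stream(seeds[2L])
  kinetics <- rng_stream(seeds[3L])
  for (s in seq_len(burn_in)) {
    state <- update_crosslinks(state, kinetics)
    state <- step_dynamics(state, thermal)
  }
  n_snap <- floor(total_steps / sample_every)
  snapshots <- vector("list", n_snap)
  times <- numeric(n_snap)
  k <- 0L
  for (s in seq_len(total_steps)) {
    state <- update_crosslinks(state, kinetics)
    state <- step_dynamics(state, thermal)
    if (s %% sample_every == 0L) {
      k <- k + 1L
      snapshots[[k]] <- state$pos
      times[k] <- state$time
    }
  }
  structure(list(snapshots = snapshots, times = times,
                 rdna_idx = state$rdna_idx,
                 completed_lifetimes = state$completed_lifetimes,
                 completed_created = state$completed_created,
                 n_active_links = nrow(state$links),
                 params = params, seed = as.integer(seed),
                 burn_in = as.integer(burn_in),
                 sample_every = as.integer(sample_every)),
            class = "polymer_trajectory")
}

#' Radius of gyration of the rDNA beads in each snapshot
#'
#' @param traj a `polymer_trajectory`.
#' @return numeric vector, one Rg (nm) per snapshot.
#' @export
rdna_rg <- function(traj) {
  vapply(traj$snapshots, function(s) {
    r <- s[traj$rdna_idx, , drop = FALSE]
    c0 <- colMeans(r)
    sqrt(mean(rowSums((r - matrix(c0, nrow(r), 3L, byrow = TRUE))^2)))
  }, numeric(1L))
}

#' Convert a trajectory snapshot to fluorophores
#'
#' rDNA beads become single fluorophores in the requested channel
#' (by default recentred on their centroid so the locus sits at the centre
#' of the rendered field).
#'
#' @param traj a `polymer_trajectory`.
#' @param snapshot snapshot index.
#' @param channel channel label (default `"red"`).
#' @param center recentre on the rDNA centroid (default `TRUE`).
#' @return a [fluorophore_set()].
#' @export
fluorophores_from_snapshot <- function(traj, snapshot, channel = "red",
                                       center = TRUE) {
  s <- traj$snapshots[[snapshot]]
  r <- s[traj$rdna_idx, , drop = FALSE]
  if (center) r <- r - matrix(colMeans(r), nrow(r), 3L, byrow = TRUE)
  fluorophore_set(r[, 1L], r[, 2L], r[, 3L], channel = channel,
                  provenance = list(mu = traj$params$mu, seed = traj$seed,
                                    snapshot = snapshot))
}

#' Write a trajectory as CSV snapshots plus a JSON manifest
#'
#' One CSV per snapshot with columns
#' `bead_index, x_nm, y_nm, z_nm, is_rdna`, and a `manifest.json` recording
#' parameters, seed and sample times.
#'
#' @param traj a `polymer_trajectory`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_rdna <- seq_len(traj$params$n_beads) %in% traj$rdna_idx
  for (k in seq_along(traj$snapshots)) {
    s <- traj$snapshots[[k]]
    utils::write.csv(
      data.frame(bead_index = seq_len(nrow(s)), x_nm = s[, 1L],
                 y_nm = s[, 2L], z_nm = s[, 3L],
                 is_rdna = as.integer(is_rdna)),
      file.path(dir, sprintf("snapshot_%04d.csv", k)), row.names = FALSE)
  }
  jsonlite::write_json(
    list(params = unclass(traj$params), seed = traj$seed,
         times = traj$times, burn_in = traj$burn_in,
         sample_every = traj$sample_every),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
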