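# Coarse-grained self-assembly surrogate and the trajectory analytics:
# cluster partitions, dense-hydrophobic-core counting, interaction-pair
# classification, radius of gyration.

.min_image <- function(d, box) d - box * round(d / box)

.pair_dists <- function(coords, box) {
  # full min-image distance matrix (B x B); B stays small at desk scale
  dx <- .min_image(outer(coords[, 1], coords[, 1], "-"), box)
  dy <- .min_image(outer(coords[, 2], coords[, 2], "-"), box)
  dz <- .min_image(outer(coords[, 3], coords[, 3], "-"), box)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Coarse-grained chain topology for a peptide
#'
#' Compresses the peptide into `n_beads` backbone beads (consecutive
#' residue groups) plus one hydrophobic tail bead for the lipid conjugate,
#' anchored to the bead holding the conjugation site. Each backbone bead
#' carries the majority polarity class of its residues (ties go
#' hydrophilic) and the summed side-chain charge at mildly acidic pH
#' (R/K +1, D/E -1, His +0.5 for its partial protonation at pH 6.7; a
#' conjugated Lys is neutral and hydrophobic).
#'
#' @param spec A [peptide_spec()].
#' @param n_beads Number of backbone beads.
#' @return Data frame per bead: `bead`, `class`, `charge`, `bonded_to`
#'   (previous bead index or NA), `is_tail`.
#' @export
chain_topology <- function(spec = liraglutide(), n_beads = 8L) {
  L <- length(spec$residues)
  stopifnot(n_beads >= 2L, n_beads <= L)
  groups <- split(seq_len(L), cut(seq_len(L), n_beads, labels = FALSE))
  mod_sites <- vapply(spec$modifications, function(m) m$site, numeric(1))
  chg_table <- c(R = 1, K = 1, D = -1, E = -1, H = 0.5)
  beads <- lapply(seq_along(groups), function(g) {
    sites <- groups[[g]]
    cls <- vapply(sites, function(s) classify_residue(spec, s), character(1))
    chg <- sum(vapply(sites, function(s) {
      if (s %in% mod_sites) 0 else {
        v <- chg_table[spec$residues[s]]
        if (is.na(v)) 0 else v
      }
    }, numeric(1)))
    data.frame(bead = g,
               class = if (sum(cls == "hydrophobic") >
                           length(cls) / 2) "hydrophobic" else "hydrophilic",
               charge = chg,
               bonded_to = if (g > 1L) g - 1L else NA_integer_,
               is_tail = FALSE)
  })
  topo <- do.call(rbind, beads)
  if (length(mod_sites)) {
    anchor <- which(vapply(groups, function(g) any(mod_sites %in% g),
                           logical(1)))[1]
    topo <- rbind(topo, data.frame(bead = n_beads + 1L, class = "hydrophobic",
                                   charge = 0, bonded_to = anchor,
                                   is_tail = TRUE))
  }
  topo
}

#' Interaction parameters of the assembly surrogate
#'
#' @param eps_hh Hydrophobic-hydrophobic attraction depth (reduced energy).
#' @param r_hh Hydrophobic attraction range (nm).
#' @param eps_pp Short-range hydrophilic-hydrophilic attraction depth
#'   (hydrogen-bond-like).
#' @param r_pp Its range (nm).
#' @param coulomb Screened-electrostatics prefactor (reduced units).
#' @param lambda Debye screening length (nm).
#' @param a_rep Soft-core repulsion strength.
#' @param r_rep Repulsive core diameter (nm).
#' @param kT Reduced thermal energy setting the diffusion scale (the
#'   `temperature` factor of [simulate_assembly()] multiplies it).
#' @param k_bond Bond spring constant.
#' @param bond_len Equilibrium bond length (nm).
#' @param cutoff Nonbonded interaction cutoff (nm).
#' @return List of class `assembly_params`.
#' @export
assembly_params <- function(eps_hh = 6, r_hh = 0.7, eps_pp = 1.5, r_pp = 0.55,
                            coulomb = 1, lambda = 0.8, a_rep = 40,
                            r_rep = 0.47, kT = 0.3, k_bond = 100,
                            bond_len = 0.5, cutoff = 1.6) {
  structure(as.list(environment()), class = "assembly_params")
}

#' Simulate coarse-grained chain self-assembly
#'
#' Overdamped Langevin dynamics of bead chains in a periodic cubic box.
#' Chains are placed with a minimum initial separation of 2 nm between
#' chain centers. Hydrophobic beads attract each other at short range
#' (lipid tails and apolar patches drive micelle-like association);
#' hydrophilic beads interact through screened electrostatics plus a weak
#' short-range attraction (hydrogen-bond network surrogate); all beads
#' share a soft repulsive core. This engine is a desk-scale surrogate for
#' a production coarse-grained force field: its role is to produce
#' trajectories with the right qualitative phenomenology for the analysis
#' operators, not to reproduce physical energetics.
#'
#' @param n_chains Number of chains (>= 1).
#' @param box Cubic box edge in nm.
#' @param steps Number of integration steps.
#' @param dt Time step (reduced units).
#' @param temperature Temperature factor (noise scale; 1 = baseline).
#' @param params An [assembly_params()].
#' @param spec Peptide whose [chain_topology()] is used.
#' @param n_beads Backbone beads per chain.
#' @param save_every Save a frame every this many steps.
#' @param seed Optional RNG seed.
#' @return Object of class `assembly_trajectory`: list of frames, each with
#'   `coords` (B x 3 matrix, nm), `box`, `beads` (chain, bead, class,
#'   charge, is_tail), `step`.
#' @export
simulate_assembly <- function(n_chains = 30L, box = 26.22, steps = 2000L,
                              dt = 1e-3, temperature = 1,
                              params = assembly_params(),
                              spec = liraglutide(), n_beads = 8L,
                              save_every = max(1L, steps %/% 20L),
                              seed = NULL) {
  stopifnot(n_chains >= 1L, box > 0, steps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  topo <- chain_topology(spec, n_beads)
  bpc <- nrow(topo)                       # beads per chain
  B <- n_chains * bpc

  # --- initial placement: chain centers >= 2 nm apart ------------------
  centers <- matrix(NA_real_, n_chains, 3)
  placed <- 0L; tries <- 0L
  while (placed < n_chains) {
    cand <- stats::runif(3, 0, box)
    ok <- TRUE
    if (placed > 0L) {
      d <- sweep(centers[seq_len(placed), , drop = FALSE], 2, cand)
      d <- .min_image(d, box)
      ok <- all(sqrt(rowSums(d^2)) >= 2)
    }
    if (ok) { placed <- placed + 1L; centers[placed, ] <- cand }
    tries <- tries + 1L
    if (tries > 20000L)
      stop("initial placement impossible: box too small for ", n_chains,
           " chains at 2 nm separation")
  }
  coords <- matrix(NA_real_, B, 3)
  for (ch in seq_len(n_chains)) {
    pos <- centers[ch, ]
    for (b in seq_len(bpc)) {
      i <- (ch - 1L) * bpc + b
      if (is.na(topo$bonded_to[b])) coords[i, ] <- pos
      else {
        step_dir <- stats::rnorm(3); step_dir <- step_dir / sqrt(sum(step_dir^2))
        anchor <- (ch - 1L) * bpc + topo$bonded_to[b]
        coords[i, ] <- coords[anchor, ] + params$bond_len * step_dir
      }
    }
  }
  coords <- coords %% box

  beads <- data.frame(chain = rep(seq_len(n_chains), each = bpc),
                      bead = rep(topo$bead, n_chains),
                      class = rep(topo$class, n_chains),
                      charge = rep(topo$charge, n_chains),
                      is_tail = rep(topo$is_tail, n_chains))
  hh <- beads$class == "hydrophobic"
  qq <- beads$charge
  bond_i <- which(!is.na(rep(topo$bonded_to, n_chains)))
  bond_j <- (beads$chain[bond_i] - 1L) * bpc +
    rep(topo$bonded_to, n_chains)[bond_i]

  frames <- list()
  push_frame <- function(step) {
    frames[[length(frames) + 1L]] <<- structure(
      list(coords = coords, box = box, beads = beads, step = step),
      class = "assembly_frame")
  }
  push_frame(0L)

  noise_sd <- sqrt(2 * params$kT * temperature * dt)
  for (s in seq_len(steps)) {
    F <- matrix(0, B, 3)
    # bonded springs
    d <- .min_image(coords[bond_i, , drop = FALSE] -
                      coords[bond_j, , drop = FALSE], box)
    r <- sqrt(rowSums(d^2)); r[r == 0] <- 1e-9
    fb <- -params$k_bond * (r - params$bond_len) / r
    Fb <- d * fb
    for (k in 1:3)
      F[, k] <- F[, k] + tabulate_weighted(bond_i, Fb[, k], B) -
        tabulate_weighted(bond_j, Fb[, k], B)
    # nonbonded forces from the full pair field
    D <- .pair_dists(coords, box)
    diag(D) <- Inf
    within <- D < params$cutoff
    idx <- which(within & upper.tri(D), arr.ind = TRUE)
    if (nrow(idx)) {
      i <- idx[, 1]; j <- idx[, 2]
      dvec <- .min_image(coords[i, , drop = FALSE] -
                           coords[j, , drop = FALSE], box)
      r <- D[idx]
      fmag <- numeric(length(r))                 # dU/dr; positive = repulsive
      core <- r < params$r_rep
      fmag[core] <- fmag[core] +
        2 * params$a_rep / params$r_rep * (1 - r[core] / params$r_rep)
      hpair <- hh[i] & hh[j]
      fmag[hpair] <- fmag[hpair] -
        params$eps_hh * 2 * r[hpair] / params$r_hh^2 *
        exp(-(r[hpair] / params$r_hh)^2)
      ppair <- !hh[i] & !hh[j]
      fmag[ppair] <- fmag[ppair] -
        params$eps_pp * 2 * r[ppair] / params$r_pp^2 *
        exp(-(r[ppair] / params$r_pp)^2)
      qpair <- ppair & (qq[i] * qq[j] != 0)
      if (any(qpair)) {
        qp <- params$coulomb * qq[i][qpair] * qq[j][qpair]
        rq <- r[qpair]
        # force magnitude of screened coulomb, repulsive for like charges
        fmag[qpair] <- fmag[qpair] +
          qp * exp(-rq / params$lambda) * (1 / rq^2 + 1 / (rq * params$lambda))
      }
      fpair <- dvec * (fmag / r)
      for (k in 1:3) {
        F[, k] <- F[, k] + tabulate_weighted(i, fpair[, k], B) -
          tabulate_weighted(j, fpair[, k], B)
      }
    }
    coords <- (coords + dt * F +
                 noise_sd * matrix(stats::rnorm(3 * B), B, 3)) %% box
    if (s %% save_every == 0L || s == steps) push_frame(s)
  }
  structure(list(frames = frames, n_chains = n_chains, box = box,
                 beads_per_chain = bpc), class = "assembly_trajectory")
}

# weighted bincount: sum w over index groups 1..n
tabulate_weighted <- function(index, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.assembly_trajectory <- function(x, ...) {
  cat("Assembly trajectory: ", x$n_chains, " chains x ", x$beads_per_chain,
      " beads, box ", x$box, " nm, ", length(x$frames), " frames\n", sep = "")
  invisible(x)
}

#' Partition a frame into contact clusters
#'
#' Chains are nodes; two chains are connected when any inter-chain bead
#' pair lies within `cutoff` under the minimum-image convention. Clusters
#' are the connected components, so the partition always covers every chain
#' exactly once (singletons allowed).
#'
#' @param frame An `assembly_frame`.
#' @param cutoff Contact cutoff in nm.
#' @return Object of class `cluster_partition`: list with `clusters` (list
#'   of chain-id vectors), `sizes`, `n_chains`, `step`.
#' @export
find_clusters <- function(frame, cutoff = 0.6) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  chains <- frame$beads$chain
  n <- max(chains)
  D <- .pair_dists(frame$coords, frame$box)
  diag(D) <- Inf
  idx <- which(D < cutoff & upper.tri(D), arr.ind = TRUE)
  edges <- unique(data.frame(a = chains[idx[, 1]], b = chains[idx[, 2]]))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  clusters <- split(seq_len(n), comp$membership)
  clusters <- lapply(unname(clusters), as.integer)
  structure(list(clusters = clusters,
                 sizes = vapply(clusters, length, integer(1)),
                 n_chains = n, step = frame$step),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("Partition of ", x$n_chains, " chains: ",
      paste(sort(x$sizes, decreasing = TRUE), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Count dense hydrophobic cores in a frame
#'
#' Density-based clustering (DBSCAN-style) over the hydrophobic beads only:
#' a core bead has at least `min_beads` neighbors (itself included) within
#' `eps`; clusters are connected components of core beads, and
#' non-core (noise/border) beads do not found clusters. The count of dense
#' cores is the structural cluster number used to read micelle-like
#' assemblies off a frame.
#'
#' @param frame An `assembly_frame`.
#' @param eps Neighbor radius in nm.
#' @param min_beads Minimum neighborhood size for a core bead.
#' @return Integer count of dense hydrophobic cores.
#' @export
hydrophobic_core_count <- function(frame, eps = 0.8, min_beads = 5L) {
  if (eps <= 0) stop("eps must be > 0")
  sel <- which(frame$beads$class == "hydrophobic")
  if (!length(sel)) return(0L)
  D <- .pair_dists(frame$coords[sel, , drop = FALSE], frame$box)
  nb <- rowSums(D <= eps)                 # includes self (diagonal zero)
  core <- which(nb >= min_beads)
  if (!length(core)) return(0L)
  Dc <- D[core, core, drop = FALSE]
  adj <- Dc <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

#' Classify close contact pairs by polarity
#'
#' Every inter-chain bead pair within `cutoff` is tallied as hydrophobic
#' (both beads hydrophobic), hydrophilic (both hydrophilic) or hybrid
#' (mixed), separately for pairs inside one cluster (intra-cluster, the
#' oligomer core/bulk) and pairs bridging two clusters (the inter-cluster
#' interface). Percentages are per scope and sum to 100 whenever any pair
#' exists; scopes without pairs are reported absent (NA percentages).
#'
#' @param frame An `assembly_frame`.
#' @param partition A `cluster_partition` of the same frame.
#' @param cutoff Pair cutoff in nm (default 0.45, i.e. 4.5 Angstrom).
#' @return Object of class `interaction_tally`: data.frame with `scope`,
#'   `type`, `count`, `percent`.
#' @export
classify_interactions <- function(frame, partition, cutoff = 0.45) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  chains <- frame$beads$chain
  member <- integer(partition$n_chains)
  for (k in seq_along(partition$clusters))
    member[partition$clusters[[k]]] <- k
  D <- .pair_dists(frame$coords, frame$box)
  diag(D) <- Inf
  idx <- which(D < cutoff & upper.tri(D), arr.ind = TRUE)
  tally <- expand.grid(scope = c("intra", "inter"),
                       type = c("hydrophobic", "hydrophilic", "hybrid"),
                       stringsAsFactors = FALSE)
  tally$count <- 0L
  if (nrow(idx)) {
    i <- idx[, 1]; j <- idx[, 2]
    inter_chain <- chains[i] != chains[j]
    i <- i[inter_chain]; j <- j[inter_chain]
    if (length(i)) {
      hi <- frame$beads$class[i] == "hydrophobic"
      hj <- frame$beads$class[j] == "hydrophobic"
      type <- ifelse(hi & hj, "hydrophobic",
                     ifelse(!hi & !hj, "hydrophilic", "hybrid"))
      scope <- ifelse(member[chains[i]] == member[chains[j]],
                      "intra", "inter")
      tb <- table(scope, type)
      for (r in seq_len(nrow(tally))) {
        s <- tally$scope[r]; ty <- tally$type[r]
        if (s %in% rownames(tb) && ty %in% colnames(tb))
          tally$count[r] <- tb[s, ty]
      }
    }
  }
  tot <- tapply(tally$count, tally$scope, sum)
  tally$percent <- ifelse(tot[tally$scope] > 0,
                          100 * tally$count / tot[tally$scope], NA_real_)
  structure(tally, class = c("interaction_tally", "data.frame"))
}

#' Radius of gyration of a bead selection
#'
#' Mass-uniform Rg about the selection centroid. Beads are first unwrapped
#' across the periodic boundary: a proximity graph (minimum-image distance
#' below `unwrap_cutoff`) is walked breadth-first and each bead placed in
#' the image nearest its predecessor; beads disconnected from the first
#' bead's component are unwrapped to its image directly. This is exact for
#' any connected cluster smaller than half the box.
#'
#' @param frame An `assembly_frame`.
#' @param selection Bead indices (default all beads).
#' @param unwrap_cutoff Proximity-graph edge cutoff (nm).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, selection = seq_len(nrow(frame$coords)),
                               unwrap_cutoff = 1.0) {
  if (!length(selection)) stop("empty selection")
  x <- frame$coords[selection, , drop = FALSE]
  box <- frame$box
  m <- nrow(x)
  if (m > 1L) {
    D <- .pair_dists(x, box)
    un <- x
    visited <- rep(FALSE, m)
    queue <- 1L; visited[1] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- which(!visited & D[cur, ] < unwrap_cutoff)
      for (b in nb) {
        un[b, ] <- un[cur, ] + .min_image(x[b, ] - x[cur, ], box)
        visited[b] <- TRUE
        queue <- c(queue, b)
      }
    }
    if (any(!visited))
      un[!visited, ] <- sweep(.min_image(
        sweep(x[!visited, , drop = FALSE], 2, un[1, ]), box), 2, un[1, ], "+")
    x <- un
  }
  cen <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, cen)^2)))
}

#' Check that a partition conserves the chain count
#'
#' @param sizes Cluster sizes (or a `cluster_partition`).
#' @param N Expected total number of chains.
#' @return List `sum`, `pass`.
#' @export
partition_conservation <- function(sizes, N) {
  if (inherits(sizes, "cluster_partition")) sizes <- sizes$sizes
  s <- sum(sizes)
  list(sum = s, pass = s == N)
}

#' Peptide molarity of a periodic box
#'
#' @param n_chains Number of chains in the box.
#' @param edge_nm Cubic box edge in nm.
#' @return Concentration in mol/L.
#' @examples
#' box_molarity(30, 26.22) * 1000  # ~3 mM
#' @export
box_molarity <- function(n_chains, edge_nm) {
  stopifnot(n_chains >= 1, edge_nm > 0)
  n_chains / 6.02214076e23 / (edge_nm^3 * 1e-24)
}

#' Write / read a trajectory as multi-frame XYZ
#'
#' Bead labels encode chain, bead index and polarity class as
#' `C<chain>B<bead><H|P>`; the comment line carries the box edge and step.
#'
#' @param traj An `assembly_trajectory`.
#' @param path Output path.
#' @return `read_trajectory_xyz` returns an `assembly_trajectory` (bead
#'   charges are not round-tripped through XYZ and are set to 0).
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    B <- nrow(fr$coords)
    writeLines(as.character(B), con)
    writeLines(sprintf("box %.6f step %d", fr$box, fr$step), con)
    lab <- sprintf("C%dB%d%s", fr$beads$chain, fr$beads$bead,
                   ifelse(fr$beads$class == "hydrophobic", "H", "P"))
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, fr$coords[, 1],
                       fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    B <- as.integer(lines[i])
    hdr <- strsplit(lines[i + 1L], " ")[[1]]
    box <- as.numeric(hdr[2]); step <- as.integer(hdr[4])
    rec <- do.call(rbind, strsplit(lines[(i + 2L):(i + 1L + B)], " "))
    lab <- rec[, 1]
    chain <- as.integer(sub("^C([0-9]+)B.*$", "\\1", lab))
    bead <- as.integer(sub("^C[0-9]+B([0-9]+)[HP]$", "\\1", lab))
    cls <- ifelse(grepl("H$", lab), "hydrophobic", "hydrophilic")
    frames[[length(frames) + 1L]] <- structure(
      list(coords = matrix(as.numeric(rec[, 2:4]), ncol = 3), box = box,
           beads = data.frame(chain = chain, bead = bead, class = cls,
                              charge = 0, is_tail = FALSE),
           step = step),
      class = "assembly_frame")
    i <- i + 2L + B
  }
  structure(list(frames = frames, n_chains = max(frames[[1]]$beads$chain),
                 box = frames[[1]]$box,
                 beads_per_chain = sum(frames[[1]]$beads$chain == 1L)),
            class = "assembly_trajectory")
}
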