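# Independent brute-force oracles used by the derived-value tests. These are
# deliberately naive reimplementations (plain loops, no shared code paths
# with the package internals).

PROTON <- 1.007276

# exhaustive (n, z) assignment with the same support/tie rule, written as
# plain double loops over the candidate table
oracle_assign <- function(peaks, m_mono, m_avg, n_max, z_max, ppm_tol, s_min) {
  cand <- NULL
  for (p in seq_len(nrow(peaks))) {
    for (n in 1:n_max) {
      mass <- n * if (n <= 8) m_mono else m_avg
      for (z in 1:z_max) {
        theo <- (mass + z * PROTON) / z
        ppm <- (peaks$mz[p] - theo) / theo * 1e6
        if (abs(ppm) <= ppm_tol)
          cand <- rbind(cand, data.frame(peak = p, n = n, z = z, ppm = ppm))
      }
    }
  }
  if (is.null(cand)) return(NULL)
  support <- sapply(cand$n, function(n)
    length(unique(cand$peak[cand$n == n])))
  cand$support <- support
  out <- NULL
  for (p in unique(cand$peak)) {
    cc <- cand[cand$peak == p, ]
    keep <- cc[cc$support >= s_min, ]
    if (!nrow(keep)) keep <- cc
    keep <- keep[order(-keep$support, abs(keep$ppm), keep$n), ]
    out <- rbind(out, keep[1, ])
  }
  out
}

# run-length scan over a binary occupancy vector
oracle_segments <- function(occupied_states, min_gap) {
  s <- sort(unique(occupied_states))
  if (!length(s)) return(list())
  segs <- list(c(s[1], s[1]))
  for (v in s[-1]) {
    last <- segs[[length(segs)]]
    if (v - last[2] - 1 < min_gap) segs[[length(segs)]][2] <- v
    else segs[[length(segs) + 1]] <- c(v, v)
  }
  segs
}

# all-pairs fragment matching scan
oracle_match <- function(observed, ladder, ppm_tol) {
  res <- NULL
  for (m in observed) {
    best <- NULL; best_ppm <- Inf
    for (r in seq_len(nrow(ladder))) {
      ppm <- (m - ladder$mass[r]) / ladder$mass[r] * 1e6
      better <- abs(ppm) < abs(best_ppm) - 1e-12 ||
        (abs(abs(ppm) - abs(best_ppm)) <= 1e-12 && !is.null(best) &&
           ladder$type[r] == "c" && ladder$type[best] == "z")
      if (abs(ppm) <= ppm_tol && (is.null(best) || better)) {
        best <- r; best_ppm <- ppm
      }
    }
    if (!is.null(best))
      res <- rbind(res, data.frame(observed = m, type = ladder$type[best],
                                   index = ladder$index[best]))
  }
  res
}

# O(N^2 * beads^2) connected components over chains
oracle_clusters <- function(frame, cutoff) {
  chains <- frame$beads$chain
  n <- max(chains)
  adj <- matrix(FALSE, n, n)
  B <- nrow(frame$coords)
  for (i in 1:(B - 1)) for (j in (i + 1):B) {
    if (chains[i] == chains[j]) next
    d <- frame$coords[i, ] - frame$coords[j, ]
    d <- d - frame$box * round(d / frame$box)
    if (sqrt(sum(d^2)) < cutoff)
      adj[chains[i], chains[j]] <- adj[chains[j], chains[i]] <- TRUE
  }
  member <- 1:n
  repeat {
    changed <- FALSE
    for (i in 1:n) for (j in 1:n)
      if (adj[i, j] && member[j] != member[i]) {
        member[member == member[j]] <- member[i]; changed <- TRUE
      }
    if (!changed) break
  }
  sort(sapply(split(1:n, member), length), decreasing = TRUE)
}

# triple-loop interaction tally
oracle_interactions <- function(frame, member, cutoff) {
  counts <- matrix(0L, 2, 3,
                   dimnames = list(c("intra", "inter"),
                                   c("hydrophobic", "hydrophilic", "hybrid")))
  B <- nrow(frame$coords)
  for (i in 1:(B - 1)) for (j in (i + 1):B) {
    ci <- frame$beads$chain[i]; cj <- frame$beads$chain[j]
    if (ci == cj) next
    d <- frame$coords[i, ] - frame$coords[j, ]
    d <- d - frame$box * round(d / frame$box)
    if (sqrt(sum(d^2)) >= cutoff) next
    hi <- frame$beads$class[i] == "hydrophobic"
    hj <- frame$beads$class[j] == "hydrophobic"
    type <- if (hi && hj) "hydrophobic" else
      if (!hi && !hj) "hydrophilic" else "hybrid"
    scope <- if (member[ci] == member[cj]) "intra" else "inter"
    counts[scope, type] <- counts[scope, type] + 1L
  }
  counts
}

# build a bare frame from coordinates and per-bead labels
make_frame <- function(coords, chain, class, box = 100,
                       charge = rep(0, length(chain))) {
  structure(list(coords = coords, box = box,
                 beads = data.frame(chain = chain, bead = seq_along(chain),
                                    class = class, charge = charge,
                                    is_tail = FALSE),
                 step = 0L),
            class = "assembly_frame")
}

# Well-separated synthetic population over the building-block band: a
# 3-charge series per state, peak positions pairwise >= 15 Th apart, and no
# n <-> 2n degeneracy inside the default n_max search window.
separable_population_abundance <- function() {
  ab <- c(0.08, 0.10, 0.09, 0.07, 0.05)
  names(ab) <- 13:17
  ab
}

separable_charge_model <- function() {
  function(n) data.frame(z = (n - 3):(n - 1), weight = 1 / 3)
}
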