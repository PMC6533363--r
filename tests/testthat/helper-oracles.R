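# Independent oracles for the network and predominance-diagram tests. These
# reimplement the quantities under test with different algorithms (explicit
# path enumeration, exhaustive partition search, linear-algebra reaction
# balancing with scalar per-point scans) so agreement is evidence rather
# than tautology.

# --- stress centrality by explicit enumeration of all shortest paths --------
oracle_stress <- function(network) {
  g <- network$graph
  vn <- igraph::V(g)$name
  nv <- length(vn)
  out <- stats::setNames(integer(nv), vn)
  if (nv < 3) return(out)
  for (s in seq_len(nv - 1)) {
    for (t in seq(s + 1, nv)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$vpaths)
      for (p in paths) {
        interior <- setdiff(as.integer(p), c(s, t))
        out[interior] <- out[interior] + 1L
      }
    }
  }
  out
}

# --- modularity oracles ------------------------------------------------------

# explicit Newman-Girvan modularity from the adjacency matrix
oracle_Q <- function(adj, comm) {
  m2 <- sum(adj) # = 2m for a symmetric 0/1 matrix
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(adj)
  same <- outer(comm, comm, "==")
  sum((adj - outer(deg, deg) / m2) * same) / m2
}

# all set partitions of n elements as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# best modularity over every partition (exhaustive; n <= 8 only)
oracle_best_modularity <- function(network) {
  adj <- igraph::as_adjacency_matrix(network$graph, sparse = FALSE)
  adj <- (adj > 0) + 0
  n <- nrow(adj)
  stopifnot(n <= 8)
  best <- -Inf
  for (p in all_partitions(n)) best <- max(best, oracle_Q(adj, p))
  best
}

# independent greedy agglomeration with the same deterministic tie-break
# (lexicographically first community pair), using the explicit Q formula
oracle_greedy_Q <- function(network) {
  adj <- igraph::as_adjacency_matrix(network$graph, sparse = FALSE)
  adj <- (adj > 0) + 0
  n <- nrow(adj)
  comm <- seq_len(n)
  q <- oracle_Q(adj, comm)
  repeat {
    pairs <- NULL
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (adj[i, j] > 0 && comm[i] != comm[j])
          pairs <- rbind(pairs, range(c(comm[i], comm[j])))
      }
    }
    if (is.null(pairs)) break
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    gains <- apply(pairs, 1, function(pr) {
      trial <- comm
      trial[trial == pr[2]] <- pr[1]
      oracle_Q(adj, trial) - q
    })
    best <- which.max(gains)
    if (gains[best] <= 1e-12) break
    comm[comm == pairs[best, 2]] <- pairs[best, 1]
    q <- q + gains[best]
  }
  oracle_Q(adj, comm)
}

# seeded random test graphs (possibly disconnected) as edge-list networks
random_toy_network <- function(n, p, seed) {
  set.seed(seed)
  pr <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pr)) < p
  if (!any(keep)) keep[1] <- TRUE
  gen_toy_network("custom",
                  edges = data.frame(from = letters[pr[1, keep]],
                                     to = letters[pr[2, keep]]))
}

# --- per-point predominance oracle ------------------------------------------

# balance `x1 base + x2 ligand + x3 H2O + x4 H+ + x5 e- = species` by solving
# a small linear system over (element, ligand element, O, H, charge), instead
# of the closed-form coefficient derivation used by the implementation
oracle_balance <- function(db, species, base, element,
                           ligand = NULL, ligand_element = NULL) {
  comp <- function(nm) {
    sp <- db$species[[nm]]
    ct <- function(e) if (e %in% names(sp$elements)) sp$elements[[e]] else 0
    c(main = ct(element),
      lig = if (is.null(ligand_element)) 0 else ct(ligand_element),
      O = ct("O"), H = ct("H"), charge = sp$charge)
  }
  cols <- list(base = comp(base),
               ligand = if (is.null(ligand)) c(0, 0, 0, 0, 0) else comp(ligand),
               H2O = c(0, 0, 1, 2, 0), Hplus = c(0, 0, 0, 1, 1),
               eminus = c(0, 0, 0, 0, -1))
  A <- do.call(cbind, cols)
  if (is.null(ligand)) { # drop the unused ligand column and its row
    A <- A[rownames(A) != "lig", colnames(A) != "ligand"]
    x <- solve(A, comp(species)[names(comp(species)) != "lig"])
    x <- c(x[1], ligand = 0, x[2:4])
  } else {
    x <- solve(A, comp(species))
  }
  names(x) <- c("base", "ligand", "H2O", "Hplus", "eminus")
  dgf <- function(nm) db$species[[nm]]$dGf
  dG <- dgf(species) - x["base"] * dgf(base) -
    (if (is.null(ligand)) 0 else x["ligand"] * dgf(ligand)) -
    x["H2O"] * dgf("H2O")
  c(x, logK = unname(-dG / thermo_constants()$lnK_factor))
}

# log activity of `species` given log activities of base and ligand; the
# balanced reaction puts H+ and e- on the left, so their activities multiply
# the denominator of the mass-action quotient
oracle_log_a <- function(cf, pH, pe, la_base, la_lig = 0) {
  unname(cf["logK"] + cf["base"] * la_base + cf["ligand"] * la_lig -
           cf["Hplus"] * pH - cf["eminus"] * pe)
}

# predominant ligand-subsystem species at one (pH, Eh) point
oracle_ligand_label <- function(system, pH, Eh) {
  db <- system$db
  pe <- Eh * system$const$F_kj / system$const$lnK_factor
  lt <- system$log_ligand_activity
  cf <- lapply(c(system$aqueous, system$solids), oracle_balance,
               db = db, base = system$ref, element = system$element)
  names(cf) <- c(system$aqueous, system$solids)
  best <- NULL; best_viol <- Inf; best_solid <- NULL
  for (p in system$aqueous) {
    # reference activity putting candidate p exactly at the total activity;
    # the balanced reaction is `x base + ... = p` so la_p = logK + x*la_ref...
    la_ref <- (lt - cf[[p]]["logK"] + cf[[p]]["Hplus"] * pH +
                 cf[[p]]["eminus"] * pe) / cf[[p]]["base"]
    viol <- -Inf
    for (q in setdiff(system$aqueous, p))
      viol <- max(viol, oracle_log_a(cf[[q]], pH, pe, la_ref) - lt)
    if (viol < best_viol - 1e-9) {
      best <- p; best_viol <- viol
      si <- vapply(system$solids, function(s)
        oracle_log_a(cf[[s]], pH, pe, la_ref), numeric(1))
      best_solid <- if (length(si) && max(si) > 1e-9)
        system$solids[which.max(si)] else NULL
    }
  }
  if (is.null(best_solid)) best else best_solid
}

# predominant gold species at one (pH, Eh) point and solubility threshold
oracle_au_label <- function(system, pH, Eh, log_a_au) {
  db <- system$db
  pe <- Eh * system$const$F_kj / system$const$lnK_factor
  lig <- oracle_ligand_label(system, pH, Eh)
  la_lig <- if (db$species[[lig]]$phase %in% c("solid", "liquid")) 0 else
    system$log_ligand_activity
  la <- vapply(system$au_aqueous, function(sp) {
    cf <- oracle_balance(db, sp, base = "Au(s)", element = "Au",
                         ligand = lig, ligand_element = system$element)
    oracle_log_a(cf, pH, pe, la_base = 0, la_lig = la_lig)
  }, numeric(1))
  if (max(la) < log_a_au) "Au(s)" else system$au_aqueous[which.max(la)]
}
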