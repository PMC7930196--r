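#' Synthetic tip-dated mitogenome samples
#'
#' Two generators with known ground truth. Genealogy mode reproduces the
#' persistent-ancestor scenario: one ancestral lineage of age T survives
#' unmutated in the population, and sampled modern tips are either exact
#' copies of it or derived lineages carrying Poisson numbers of private
#' mutations. Coalescent mode draws a serial-sample haploid coalescent
#' genealogy under a piecewise-exponential demography and scatters
#' mutations on its branches.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param L number of sites (default 16,569).
#' @param mu_site mutation rate per site per year (default 1.6e-8, in the
#'   middle of the published germline estimates).
#' @param generation_years years per generation (default 25).
#' @param demography data.frame `time_bp, size`: effective (female)
#'   population-size breakpoints, exponentially interpolated between
#'   breakpoints and constant beyond the oldest. The default is an
#'   ancestral size of 5,000 growing 20-fold over the last 10,000 years.
#' @param sampling data.frame `age_bp, n`: serial sampling tiers; ages
#'   from -50 (modern, 2000 AD) to ~45,000 BP.
#' @param persistent_fraction genealogy mode: fraction of modern tips
#'   that are unmutated copies of the ancestral lineage.
#' @param divergence genealogy mode: when derived lineages split from the
#'   persistent ancestor. `"ancestral"` splits all of them at the
#'   ancestor's age T (private counts ~ Poisson(mu*L*T));
#'   `"uniform"` spreads split times uniformly over `[0, T]`, the
#'   genealogy scenario in which derived lineages sprout from the
#'   persistent lineage in different generations.
#' @param clades coalescent mode: number of deepest clades used as
#'   haplogroup stand-ins (labelled M, N, R, ...).
#' @param seed default RNG seed for the simulators.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(L = MITO_LENGTH,
                              mu_site = 1.6e-8,
                              generation_years = 25,
                              demography = data.frame(
                                time_bp = c(0, 10000, 300000),
                                size = c(100000, 5000, 5000)),
                              sampling = data.frame(
                                age_bp = c(-50, 1000, 5000, 15000, 30000,
                                           45000),
                                n = c(20, 4, 4, 4, 4, 4)),
                              persistent_fraction = 0,
                              divergence = c("ancestral", "uniform"),
                              clades = 3,
                              seed = 1L) {
  divergence <- match.arg(divergence)
  stopifnot(L >= 1, mu_site >= 0, generation_years > 0,
            is.data.frame(demography),
            all(c("time_bp", "size") %in% names(demography)),
            is.data.frame(sampling),
            all(c("age_bp", "n") %in% names(sampling)))
  if (any(demography$size < 1)) {
    stop("demography sizes must be >= 1")
  }
  if (any(sampling$n < 1)) {
    stop("sampling tier counts must be >= 1")
  }
  if (any(sampling$age_bp < -70)) {
    stop("sampling ages must be >= -70 BP")
  }
  if (persistent_fraction < 0 || persistent_fraction > 1) {
    stop("persistent_fraction must lie in [0, 1]")
  }
  demography <- demography[order(demography$time_bp), ]
  structure(list(L = as.integer(L), mu_site = mu_site,
                 generation_years = generation_years,
                 demography = demography, sampling = sampling,
                 persistent_fraction = persistent_fraction,
                 divergence = divergence, clades = as.integer(clades),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate the persistent-ancestor genealogy
#'
#' Emits one ancestral profile at age `T` (the single positive-age
#' sampling tier, one individual) and `n` modern tips (the modern tier).
#' Each tip is an exact copy of the ancestor with probability
#' `persistent_fraction`; otherwise it diverged from the ancestral
#' lineage `s` years ago (`s = T` under `divergence = "ancestral"`,
#' `s ~ U(0, T)` under `"uniform"`) and carries
#' `K ~ Poisson(mu_site * L * s)` private substitutions at fresh,
#' previously unused positions, so counts are exact (no recurrent hits).
#'
#' @param config a [simulation_config()] whose `sampling` has exactly one
#'   tier with positive age (the ancestor) and one modern tier.
#' @param seed RNG seed (default `config$seed`).
#' @param reference a [mito_reference()] supplying reference alleles.
#' @return list with `profiles` (named list, ancestor first) and `truth`
#'   (ancestor age, per-tip divergence times and mutation counts,
#'   persistent flags, expected count `mu_site * L * T`, seed, config).
#' @export
simulate_genealogy <- function(config, seed = config$seed,
                               reference = synthetic_reference()) {
  old <- config$sampling[config$sampling$age_bp > 0, ]
  new <- config$sampling[config$sampling$age_bp <= 0, ]
  if (nrow(old) != 1L || nrow(new) != 1L) {
    stop("genealogy mode needs exactly one positive-age tier (the ",
         "ancestor) and one modern tier")
  }
  T_anc <- old$age_bp
  n <- new$n
  set.seed(seed)
  persistent <- stats::runif(n) < config$persistent_fraction
  s <- ifelse(persistent, 0,
              if (config$divergence == "ancestral") T_anc
              else stats::runif(n, 0, T_anc))
  K <- ifelse(persistent, 0L,
              stats::rpois(n, config$mu_site * config$L * s))
  total <- sum(K)
  if (total > config$L) {
    stop("more mutations demanded (", total, ") than free sites (",
         config$L, ")")
  }
  positions <- sample.int(config$L, total)
  split_idx <- rep(seq_len(n), K)
  profiles <- vector("list", n + 1L)
  profiles[[1]] <- mito_profile("ANC", T_anc, "M", "M")
  for (i in seq_len(n)) {
    pos <- positions[split_idx == i]
    v <- if (length(pos)) {
      ref <- reference$bases[pos]
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      variant_table(pos, ref, alt, "substitution")
    } else {
      variant_table()
    }
    profiles[[i + 1L]] <- mito_profile(sprintf("T%03d", i), new$age_bp,
                                       "M", "M", v)
  }
  names(profiles) <- vapply(profiles, `[[`, "", "id")
  truth <- list(mode = "genealogy", T_anc = T_anc, mu_site = config$mu_site,
                L = config$L, expected_K = config$mu_site * config$L * T_anc,
                divergence_times = s, K = as.integer(K),
                persistent = persistent, seed = as.integer(seed),
                config_hash = config_hash(config))
  list(profiles = profiles, truth = truth, config = config)
}

#' Simulate a serial-sample coalescent with demography
#'
#' Builds a haploid coalescent genealogy over the tip-dated sampling
#' tiers under the piecewise-exponential demography, scatters mutations
#' on branches as Poisson(branch years * mu_site * L) at uniformly drawn
#' positions (recurrent hits allowed, so observed counts slightly
#' undercount true events), and labels tips by the deepest `clades`
#' subtrees as haplogroup stand-ins.
#'
#' @inheritParams simulate_genealogy
#' @return list with `profiles` (tips), and `truth` carrying the true
#'   tree (`data.frame node, parent, time_gens`), TMRCA, clade labels,
#'   per-clade root haplotypes and ages, seed, config hash.
#' @export
simulate_coalescent <- function(config, seed = config$seed,
                                reference = synthetic_reference()) {
  set.seed(seed)
  g <- config$generation_years
  base_age <- min(config$sampling$age_bp)

  tip_ages <- rep(config$sampling$age_bp, config$sampling$n)
  tier <- rep(seq_len(nrow(config$sampling)), config$sampling$n)
  n_tips <- length(tip_ages)
  tip_times <- (tip_ages - base_age) / g

  demo <- demography_gens(config$demography, base_age, g)
  tree <- sample_serial_coalescent(tip_times, demo)

  # mutations per branch, then states by depth-first descent from the root
  root <- which(is.na(tree$parent))
  n_nodes <- nrow(tree)
  branch_years <- (tree$time_gens[tree$parent] - tree$time_gens) * g
  branch_years[root] <- 0
  n_mut <- stats::rpois(n_nodes, pmax(branch_years, 0) *
                          config$mu_site * config$L)
  mut_pos <- lapply(n_mut, function(m) {
    if (m > 0) sample.int(config$L, m, replace = TRUE) else integer()
  })

  children <- split(seq_len(n_nodes)[-root], tree$parent[-root])
  clade <- assign_clades(tree, root, n_tips, config$clades)

  tip_states <- vector("list", n_tips)
  clade_roots <- list()
  descend <- function(node, state) {
    for (pos in mut_pos[[node]]) {
      cur <- state[[as.character(pos)]]
      if (is.null(cur)) {
        cur <- reference$bases[pos]
      }
      alt <- sample(setdiff(DNA_BASES, cur), 1L)
      if (alt == reference$bases[pos]) {
        state[[as.character(pos)]] <- NULL   # back-mutation to reference
      } else {
        state[[as.character(pos)]] <- alt
      }
    }
    if (!is.null(clade$root_nodes) && node %in% clade$root_nodes) {
      clade_roots[[clade$labels[match(node, clade$root_nodes)]]] <<-
        state_to_variants(state, reference)
    }
    if (node <= n_tips) {
      tip_states[[node]] <<- state
    } else {
      for (ch in children[[as.character(node)]]) {
        descend(ch, state)
      }
    }
  }
  descend(root, list())

  profiles <- lapply(seq_len(n_tips), function(i) {
    mito_profile(sprintf("S%03d", i), tip_ages[i],
                 clade$tip_haplogroup[i],
                 clade$tip_macro[i],
                 state_to_variants(tip_states[[i]], reference))
  })
  names(profiles) <- vapply(profiles, `[[`, "", "id")

  truth <- list(mode = "coalescent",
                tree = tree, root = root,
                tmrca_gens = tree$time_gens[root],
                tmrca_years_bp = tree$time_gens[root] * g + base_age,
                tip_tier = tier,
                clade_labels = clade$labels,
                tip_clade = clade$tip_clade,
                clade_root_ages_bp = tree$time_gens[clade$root_nodes] * g +
                  base_age,
                clade_root_variants = clade_roots,
                mu_site = config$mu_site, L = config$L,
                seed = as.integer(seed),
                config_hash = config_hash(config))
  list(profiles = profiles, truth = truth, config = config)
}

# demography in generations before the youngest sample; the breakpoint
# grid is re-anchored so that it starts exactly at time 0
demography_gens <- function(demography, base_age, g) {
  t_gens <- (demography$time_bp - base_age) / g
  size <- demography$size
  if (all(t_gens <= 0)) {
    return(list(time = 0, size = size[length(size)]))
  }
  if (t_gens[1] > 0) {           # extend the most recent size back to 0
    t_gens <- c(0, t_gens)
    size <- c(size[1], size)
  } else if (t_gens[1] < 0) {    # interpolate the size at time 0
    i <- max(which(t_gens < 0))
    frac <- (0 - t_gens[i]) / (t_gens[i + 1L] - t_gens[i])
    s0 <- size[i] * (size[i + 1L] / size[i])^frac
    keep <- t_gens > 0
    t_gens <- c(0, t_gens[keep])
    size <- c(s0, size[keep])
  }
  list(time = t_gens, size = size)
}

# Ne at time t (generations), piecewise-exponential interpolation
ne_at <- function(t, demo) {
  i <- findInterval(t, demo$time)
  if (i >= length(demo$time)) {
    return(demo$size[length(demo$size)])
  }
  t0 <- demo$time[i]
  t1 <- demo$time[i + 1L]
  demo$size[i] * (demo$size[i + 1L] / demo$size[i])^((t - t0) / (t1 - t0))
}

# Draw the next coalescence time for k lineages starting at time t,
# capped at `cap`; returns Inf if no event occurs before the cap.
# Walks demography pieces; within each piece Ne is exponential, so the
# integrated pair-coalescence intensity has a closed form.
draw_coalescence <- function(t, k, demo, cap = Inf) {
  pair_rate <- k * (k - 1) / 2
  if (pair_rate <= 0) {
    return(Inf)
  }
  breaks <- demo$time[demo$time > t & demo$time < cap]
  bounds <- c(t, breaks, cap)
  for (j in seq_len(length(bounds) - 1L)) {
    s0 <- bounds[j]
    s1 <- bounds[j + 1L]
    n0 <- ne_at(s0, demo)
    grow <- if (is.finite(s1)) {
      log(ne_at(s1, demo) / n0) / (s1 - s0)
    } else {
      0
    }
    e <- stats::rexp(1)
    if (abs(grow) < 1e-12) {
      delta <- e * n0 / pair_rate
      if (s0 + delta <= s1) {
        return(s0 + delta)
      }
    } else {
      arg <- 1 - e * n0 * grow / pair_rate
      if (arg > 0) {
        delta <- -log(arg) / grow
        if (s0 + delta <= s1) {
          return(s0 + delta)
        }
      }
      # arg <= 0 means the integrated intensity of this piece is
      # exhausted before e: no event here
    }
  }
  Inf
}

# Serial-sample coalescent: tips at `tip_times` (generations before the
# youngest), returns a table of nodes (tips first) with parent and time.
sample_serial_coalescent <- function(tip_times, demo) {
  n <- length(tip_times)
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  time <- c(tip_times, rep(NA_real_, n - 1L))
  next_node <- n + 1L

  pending <- order(tip_times)        # tips not yet activated
  active <- integer()
  t <- NULL
  while (length(pending) || length(active) > 1L) {
    if (is.null(t)) {
      t <- tip_times[pending[1]]
    }
    at_now <- pending[tip_times[pending] <= t + 1e-12]
    active <- c(active, at_now)
    pending <- setdiff(pending, at_now)
    if (length(active) < 2L) {
      t <- if (length(pending)) tip_times[pending[1]] else t
      next
    }
    cap <- if (length(pending)) tip_times[pending[1]] else Inf
    tc <- draw_coalescence(t, length(active), demo, cap)
    if (tc <= cap) {
      pick <- sample(length(active), 2L)
      node <- next_node
      next_node <- next_node + 1L
      parent[active[pick]] <- node
      time[node] <- tc
      active <- c(active[-pick], node)
      t <- tc
    } else {
      t <- cap
    }
  }
  data.frame(node = seq_len(n_nodes), parent = parent, time_gens = time)
}

# The `k` deepest subtrees: remove the k-1 oldest coalescences (the
# backbone); clade roots are their non-backbone children.
assign_clades <- function(tree, root, n_tips, k) {
  internal <- which(tree$node > n_tips)
  k <- max(1L, min(k, n_tips))
  if (k == 1L || length(internal) < k - 1L) {
    lab <- clade_letters(1L)
    return(list(labels = lab, root_nodes = root,
                tip_clade = rep(1L, n_tips),
                tip_haplogroup = rep(lab, n_tips),
                tip_macro = rep(macro_of(lab), n_tips)))
  }
  backbone <- internal[order(tree$time_gens[internal],
                             decreasing = TRUE)][seq_len(k - 1L)]
  root_nodes <- setdiff(which(tree$parent %in% backbone), backbone)
  labels <- clade_letters(length(root_nodes))

  # walk each tip up to the clade root containing it
  up_to_clade <- function(tip) {
    node <- tip
    while (!node %in% root_nodes) {
      node <- tree$parent[node]
      if (is.na(node)) {
        return(NA_integer_)
      }
    }
    match(node, root_nodes)
  }
  tip_clade <- vapply(seq_len(n_tips), up_to_clade, 0L)

  # sub-label by the child of the clade root the tip descends through
  tip_haplogroup <- vapply(seq_len(n_tips), function(tip) {
    cr <- root_nodes[tip_clade[tip]]
    if (tip == cr) {
      return(labels[tip_clade[tip]])
    }
    node <- tip
    while (!is.na(tree$parent[node]) && tree$parent[node] != cr) {
      node <- tree$parent[node]
    }
    kids <- sort(which(tree$parent == cr))
    paste0(labels[tip_clade[tip]], match(node, kids))
  }, "")

  list(labels = labels, root_nodes = root_nodes, tip_clade = tip_clade,
       tip_haplogroup = tip_haplogroup,
       tip_macro = vapply(labels[tip_clade], macro_of, ""))
}

clade_letters <- function(k) {
  pool <- c("M", "N", "R", "A", "B", "C", "D", "E", "F", "G")
  if (k > length(pool)) {
    pool <- c(pool, paste0("Q", seq_len(k)))
  }
  pool[seq_len(k)]
}

macro_of <- function(label) {
  if (label %in% c("M", "N", "R")) label else "L-other"
}

state_to_variants <- function(state, reference) {
  if (!length(state)) {
    return(variant_table())
  }
  pos <- as.integer(names(state))
  variant_table(pos, reference$bases[pos], unlist(state, use.names = FALSE),
                "substitution")
}

# small stable polynomial hash of the configuration (provenance field)
config_hash <- function(config) {
  x <- unclass(config)
  bytes <- utf8ToInt(paste(deparse(x[setdiff(names(x), "seed")]),
                           collapse = ""))
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Write a simulated data set as plain-text fixtures
#'
#' Writes aligned FASTA (via the reference), metadata CSV, a roots file
#' in the haplotype-table dialect (per-clade root haplotypes, coalescent
#' mode; the reference root, genealogy mode), and a truth JSON carrying
#' the seed and configuration hash. Files round-trip through
#' [read_profiles()].
#'
#' @param sim result of [simulate_genealogy()] or
#'   [simulate_coalescent()].
#' @param out_dir output directory (created if missing).
#' @param reference the [mito_reference()] the profiles refer to.
#' @return named character vector of the files written.
#' @export
write_fixture <- function(sim, out_dir,
                          reference = synthetic_reference()) {
  if (!length(sim$profiles)) {
    stop("no profiles to write")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(out_dir, "sequences.fasta"),
             metadata = file.path(out_dir, "metadata.csv"),
             roots = file.path(out_dir, "roots.txt"),
             truth = file.path(out_dir, "truth.json"))

  seqs <- Biostrings::DNAStringSet(vapply(sim$profiles, function(p) {
    paste(profile_to_sequence(p, reference), collapse = "")
  }, ""))
  names(seqs) <- names(sim$profiles)
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])

  write_metadata(sim$profiles, paths[["metadata"]])

  roots <- sim$truth$clade_root_variants
  root_lines <- if (length(roots)) {
    vapply(names(roots), function(lab) {
      keys <- variant_keys(roots[[lab]])
      if (length(keys)) paste0(lab, "\t", paste(keys, collapse = " "))
      else lab
    }, "")
  } else {
    "ROOT"            # genealogy mode: the root is the reference itself
  }
  writeLines(root_lines, paths[["roots"]])

  truth_json <- sim$truth
  truth_json$tree <- NULL      # keep the JSON small; the tree is in-memory
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Reference-aligned sequence of a profile
#'
#' Substitutions replace the reference base; deletions become gap
#' characters; insertions cannot be represented in the fixed 16,569-column
#' alignment and are dropped with a warning.
#'
#' @param profile a `mito_profile`.
#' @param reference a [mito_reference()].
#' @return character vector of 16,569 single characters.
#' @export
profile_to_sequence <- function(profile, reference) {
  bases <- reference$bases
  v <- profile$variants
  ins <- v$kind == "insertion"
  if (any(ins)) {
    warning("dropping ", sum(ins), " insertion(s) from ", profile$id,
            ": not representable in a fixed-column alignment")
    v <- v[!ins, , drop = FALSE]
  }
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "substitution") {
      bases[v$position[i]] <- v$alt[i]
    } else {
      span <- v$position[i] + seq_len(nchar(v$ref[i])) - 1L
      bases[span] <- "-"
    }
  }
  bases
}
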