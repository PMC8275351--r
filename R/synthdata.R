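#' Simulation configuration
#'
#' Parameters of the synthetic haploblock generator.  The defaults emulate
#' the statistical shape of real haploblock panels used in membership
#' inference studies: blocks of `L` linked sites carrying a sparse panel of
#' `t` haplotypes (t << 2^L), with heavy-tailed frequencies (Dirichlet
#' concentration 0.3) so that several haplotypes fall under the rare ceiling
#' (population frequency < 0.02), and target selection restricted to
#' haplotypes whose prior presence probability in a database of `N` genomes
#' is below 0.1.
#'
#' @param L sites per block.
#' @param t known haplotypes per block (for `structure = "independent"` the
#'   panel is all `2^L` patterns and `t` is ignored).
#' @param concentration Dirichlet concentration of the haplotype frequencies
#'   (smaller = heavier rare tail).
#' @param N genomes per private database.
#' @param n_blocks number of blocks in a suite.
#' @param rare_ceiling population-frequency ceiling defining "rare"
#'   haplotypes.
#' @param prior_ceiling prior-presence ceiling for target selection.
#' @param structure `"phylo"` (default): an infinite-sites perfect
#'   phylogeny -- each site's minor allele arises once on one branch of a
#'   random genealogy, so carrier sets are nested (strong LD) and every
#'   non-modal haplotype carries at least one private variant, as real
#'   haploblock panels do; `"founder"`: patterns cluster in Hamming space
#'   around a few founders with recurrent mutation allowed;
#'   `"independent"`: the panel is the full product set with per-site
#'   independent frequencies (no LD) -- the negative control for the
#'   haplotype methods' advantage.
#' @param mutation for founder structure: `"both"` flips alleles in either
#'   direction; `"drop"` only removes founder minor alleles, so every rare
#'   haplotype's minor-allele set is a subset of its founder's (no private
#'   singleton sites).
#' @param seed integer root seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(L = 20L, t = 10L, concentration = 0.3, N = 500L,
                       n_blocks = 1L, rare_ceiling = 0.02,
                       prior_ceiling = 0.1,
                       structure = c("phylo", "founder", "independent"),
                       mutation = c("both", "drop"), seed = 1L) {
  structure_ <- match.arg(structure)
  mutation <- match.arg(mutation)
  if (structure_ != "independent" && t > 2^L)
    stop("t cannot exceed 2^L distinct patterns")
  if (structure_ == "phylo" && L < t)
    stop("phylo structure needs L >= t (one private site per haplotype)")
  if (structure_ == "independent" && L > 8L)
    stop("independent structure enumerates 2^L patterns; use L <= 8")
  structure(list(L = as.integer(L), t = as.integer(t),
                 concentration = concentration, N = as.integer(N),
                 n_blocks = as.integer(n_blocks),
                 rare_ceiling = rare_ceiling, prior_ceiling = prior_ceiling,
                 structure = structure_, mutation = mutation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic haploblock
#'
#' Founder structure: a small set of founder patterns is drawn, and the
#' remaining haplotypes are founders with one or a few mutated sites, so
#' patterns cluster in Hamming space as they do inside real haploblocks.
#' Frequencies are Dirichlet-distributed with the configured concentration,
#' founders receiving the largest shares.  Per-site public minor-allele
#' frequencies are the exact panel mixture `sum_i b_ij f(x_i)`; any site
#' whose mixture exceeds 0.5 has its allele labels swapped so that 1 always
#' marks the (public) minor allele.
#'
#' @param cfg a [sim_config].
#' @param block_id block identifier.
#' @param seed seed for this block (default the config seed); generation is
#'   deterministic given the seed.
#' @return a [haploblock].
#' @export
generate_block <- function(cfg, block_id = "B1", seed = cfg$seed) {
  with_local_seed(seed, {
    if (cfg$structure == "independent") {
      L <- cfg$L
      maf <- stats::runif(L, 0.1, 0.4)
      pats <- as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE]
      dimnames(pats) <- NULL
      storage.mode(pats) <- "integer"
      f <- apply(pats, 1L, function(b) prod(ifelse(b == 1L, maf, 1 - maf)))
    } else if (cfg$structure == "phylo") {
      pats <- phylo_panel(cfg)
      g <- pmax(stats::rgamma(cfg$t, cfg$concentration), 1e-12)
      f <- sort(g / sum(g), decreasing = TRUE)
      # ancestral-like haplotypes (few minor alleles) are the common ones
      ord <- order(rowSums(pats), sample.int(cfg$t))
      pats <- pats[ord, , drop = FALSE]
    } else {
      pats <- founder_panel(cfg)
      g <- pmax(stats::rgamma(cfg$t, cfg$concentration), 1e-12)
      f <- sort(g / sum(g), decreasing = TRUE)
    }
    rownames(pats) <- paste0("hap", seq_len(nrow(pats)))
    maf_mix <- as.numeric(crossprod(pats, f))
    flip <- maf_mix > 0.5
    if (any(flip)) {
      pats[, flip] <- 1L - pats[, flip]
      maf_mix[flip] <- 1 - maf_mix[flip]
    }
    L <- ncol(pats)
    major <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    minor <- vapply(major, function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1L))
    sites <- data.frame(site_id = sprintf("%s_s%02d", block_id, seq_len(L)),
                        position = 1000L + 137L * seq_len(L),
                        major_allele = major, minor_allele = unname(minor),
                        public_maf = maf_mix)
    haploblock(block_id, sites, pats, f)
  })
}

# Infinite-sites perfect-phylogeny panel: a random genealogy over the t
# haplotypes, with each of the L sites mutating exactly once on one branch;
# a haplotype carries the minor allele at every site that mutated on its
# root path.  One haplotype is the unmutated ancestral type; every other
# haplotype's pendant branch carries at least one mutation, so each has a
# private variant.  Carrier sets are laminar -- the signature of strong LD.
phylo_panel <- function(cfg) {
  t_n <- cfg$t; L <- cfg$L
  # random binary genealogy by sequential merging; clades as leaf index sets
  groups <- as.list(seq_len(t_n))
  clades <- list()
  while (length(groups) > 1L) {
    pick <- sample.int(length(groups), 2L)
    merged <- c(groups[[pick[1L]]], groups[[pick[2L]]])
    groups[pick] <- NULL
    groups[[length(groups) + 1L]] <- merged
    if (length(merged) < t_n) clades[[length(clades) + 1L]] <- merged
  }
  ancestral <- sample.int(t_n, 1L)
  pendant <- setdiff(seq_len(t_n), ancestral)
  # the ancestral leaf is the unmutated root type: only edges below it
  # (non-ancestral pendants and clades not containing it) carry mutations
  clades <- Filter(function(cl) !(ancestral %in% cl), clades)
  edges <- c(as.list(pendant), clades)
  pats <- matrix(0L, t_n, L)
  # one guaranteed private mutation per non-ancestral haplotype
  for (q in seq_along(pendant)) pats[pendant[q], q] <- 1L
  extra <- L - length(pendant)
  if (extra > 0L) {
    w <- stats::rexp(length(edges))
    alloc <- sample.int(length(edges), extra, replace = TRUE, prob = w)
    for (q in seq_len(extra))
      pats[edges[[alloc[q]]], length(pendant) + q] <- 1L
  }
  # shuffle site order so private sites are not a recognisable prefix
  pats[, sample.int(L)]
}

# Founder patterns + mutated descendants, all distinct.  Minor alleles are
# young variants, so they ride on the rarer haplotypes: the founder taking
# the largest frequency share is sparse in minor alleles and sparsity
# decreases down the frequency ranking.  This keeps every per-site mixture
# frequency below 0.5 in the typical draw (no polarity flip needed) and
# keeps the all-major pattern out of the panel.
founder_panel <- function(cfg) {
  L <- cfg$L; t_n <- cfg$t
  nf <- max(1L, min(t_n, round(t_n / 4)))
  dens <- if (cfg$mutation == "drop") rep(0.3, nf)
          else if (nf == 1L) 0.12
          else 0.12 + 0.25 * (seq_len(nf) - 1L) / (nf - 1L)
  for (restart in 1:50) {
    seen <- character(0)
    pats <- matrix(0L, t_n, L)
    i <- 1L; tries <- 0L; stalled <- FALSE
    while (i <= t_n) {
      tries <- tries + 1L
      if (tries > 100L * t_n) { stalled <- TRUE; break }
      if (i <= nf) {
        p <- as.integer(stats::runif(L) < dens[i])
        if (sum(p) == 0L) p[sample.int(L, 1L)] <- 1L # every haplotype varies
      } else {
        base <- pats[sample.int(nf, 1L), ]
        nmut <- 1L + stats::rpois(1L, 0.7)
        p <- base
        if (cfg$mutation == "drop") {
          ones <- which(base == 1L)
          if (length(ones) < 2L) next      # keep at least one minor allele
          drop <- sample(ones, min(nmut, length(ones) - 1L))
          p[drop] <- 0L
        } else {
          flip <- sample.int(L, min(nmut, L))
          p[flip] <- 1L - p[flip]
        }
      }
      key <- paste0(p, collapse = "")
      if (key %in% seen) next
      seen <- c(seen, key)
      pats[i, ] <- p
      i <- i + 1L
    }
    if (!stalled) return(pats)
  }
  stop("cannot place ", t_n, " distinct patterns at L = ", L)
}

#' Sample a private database from a haploblock
#'
#' Draws the 2N haplotypes of a database of `N` genomes multinomially from
#' the block's public frequencies.  Optional forcing then adjusts counts so
#' that every `forced_in` haplotype has count >= 1 and every `forced_out`
#' haplotype has count 0, moving the difference to/from the most common
#' unforced haplotype -- the standard way to plant rare targets whose
#' spontaneous inclusion probability is negligible.
#'
#' @param block a [haploblock].
#' @param N database genome count.
#' @param forced_in,forced_out disjoint character vectors of haplotype ids.
#' @param seed integer seed.
#' @return a [genome_db] over the block's patterns.
#' @export
sample_database <- function(block, N, forced_in = NULL, forced_out = NULL,
                            seed = NULL) {
  if (length(intersect(forced_in, forced_out)))
    stop("forced_in and forced_out must be disjoint")
  ids <- rownames(block$patterns)
  bad <- setdiff(c(forced_in, forced_out), ids)
  if (length(bad)) stop("unknown haplotype id '", bad[1L], "'")
  counts <- as.integer(with_local_seed(seed,
    stats::rmultinom(1L, 2L * N, block$frequencies)))
  names(counts) <- ids
  free <- setdiff(ids, c(forced_in, forced_out))
  for (id in forced_out) {
    if (counts[id] > 0L) {
      if (!length(free)) stop("no unforced haplotype to absorb counts; ",
                              "use larger t or different forcing")
      donor <- free[which.max(counts[free])]
      counts[donor] <- counts[donor] + counts[id]
      counts[id] <- 0L
    }
  }
  for (id in forced_in) {
    if (counts[id] == 0L) {
      donors <- free[counts[free] > 0L]
      if (!length(donors)) stop("cannot force '", id, "' in: no counts to ",
                                "borrow; use larger N")
      donor <- donors[which.max(counts[donors])]
      counts[donor] <- counts[donor] - 1L
      counts[id] <- 1L
    }
  }
  genome_db(N, block$patterns, counts)
}

#' Set the exact count of one haplotype in a database
#'
#' Moves the difference to or from the most common other haplotype, keeping
#' the total at 2N.  Used by leave-one-out fixtures that plant a novel
#' haplotype at a prescribed count.
#'
#' @param db a [genome_db].
#' @param haplotype_id row name of the pattern in `db$patterns`.
#' @param count desired count.
#' @return the adjusted [genome_db].
#' @export
set_haplotype_count <- function(db, haplotype_id, count) {
  i <- match(haplotype_id, rownames(db$patterns))
  if (is.na(i)) stop("unknown haplotype '", haplotype_id, "'")
  counts <- db$counts
  diff <- as.integer(count) - counts[i]
  if (diff != 0L) {
    j <- setdiff(order(counts, decreasing = TRUE), i)[1L]
    if (counts[j] - diff < 0L) stop("cannot rebalance counts")
    counts[j] <- counts[j] - diff
    counts[i] <- counts[i] + diff
  }
  genome_db(db$n_genomes, db$patterns, counts)
}

#' Select rare target haplotypes of a block
#'
#' @param block a [haploblock].
#' @param N database genome count (sets the prior).
#' @param prior_ceiling keep haplotypes with prior presence below this.
#' @param n_max at most this many (rarest first).
#' @return character vector of haplotype ids.
#' @export
rare_targets <- function(block, N, prior_ceiling = 0.1, n_max = Inf) {
  pri <- prior_presence(block$frequencies, N)
  ids <- rownames(block$patterns)[pri < prior_ceiling]
  f <- block$frequencies[pri < prior_ceiling]
  utils::head(ids[order(f)], n_max)
}

#' Write a reproducible fixture suite to disk
#'
#' Generates `cfg$n_blocks` haploblocks with one sampled database each,
#' writes the haploblock JSON, frequency-table TSV, Beacon-table TSV and
#' ground-truth database JSON per block, plus a `manifest.json` listing every
#' selected rare target with its truth label (present/absent in the
#' database), for use by power and false-positive harnesses.
#'
#' @param cfg a [sim_config].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
make_fixture_suite <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- list()
  for (b in seq_len(cfg$n_blocks)) {
    bid <- sprintf("SB%03d", b)
    blk <- generate_block(cfg, bid, seed = cfg$seed + b)
    db <- sample_database(blk, cfg$N, seed = cfg$seed + 10000L + b)
    ft <- summarize_database(db, blk, "frequency")
    bt <- summarize_database(db, blk, "beacon")
    write_haploblock(blk, file.path(out_dir, paste0(bid, ".block.json")))
    write_freq_table(ft, file.path(out_dir, paste0(bid, ".freq.tsv")))
    write_beacon_table(bt, file.path(out_dir, paste0(bid, ".beacon.tsv")))
    jsonlite::write_json(
      list(n_genomes = db$n_genomes,
           patterns = pattern_strings(db$patterns),
           counts = db$counts),
      file.path(out_dir, paste0(bid, ".db.json")),
      auto_unbox = TRUE, digits = NA)
    tg <- rare_targets(blk, cfg$N, cfg$prior_ceiling)
    cnt <- vapply(tg, function(id)
      db$counts[match(id, rownames(db$patterns))], integer(1L))
    blocks[[b]] <- list(
      block_id = bid,
      files = list(block = paste0(bid, ".block.json"),
                   freq = paste0(bid, ".freq.tsv"),
                   beacon = paste0(bid, ".beacon.tsv"),
                   db = paste0(bid, ".db.json")),
      targets = if (length(tg))
        data.frame(haplotype_id = tg, count = cnt,
                   truth = ifelse(cnt > 0L, "present", "absent"))
      else NULL)
  }
  manifest <- list(config = unclass(cfg), blocks = blocks)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
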