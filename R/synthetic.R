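# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes; every generator returns its ground truth and is
# bit-reproducible given a seed.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# grow one random glycan tree as a nodes data frame
.random_tree_nodes <- function(n_res, alphabet, max_children = 3L,
                               max_depth = 5L) {
  name <- sample(alphabet, 1)
  nodes <- data.frame(id = 1L, name = name, anomer = NA_character_,
                      anomeric_carbon = NA_integer_, parent = NA_integer_,
                      parent_pos = NA_integer_, depth = 0L,
                      stringsAsFactors = FALSE)
  while (nrow(nodes) < n_res) {
    open <- which(vapply(nodes$id, function(i)
      sum(nodes$parent == i, na.rm = TRUE) < max_children, logical(1)) &
        nodes$depth < max_depth)
    if (!length(open)) break
    p <- if (length(open) == 1L) open else sample(open, 1)
    used <- nodes$parent_pos[!is.na(nodes$parent) & nodes$parent == p]
    free <- setdiff(2:6, used)
    if (!length(free)) next
    nm <- sample(alphabet, 1)
    nodes <- rbind(nodes, data.frame(
      id = nrow(nodes) + 1L, name = nm,
      anomer = sample(c("a", "b"), 1),
      anomeric_carbon = if (nm %in% c("Neu5Ac", "Neu5Gc")) 2L else 1L,
      parent = p, parent_pos = if (length(free) == 1L) free else sample(free, 1),
      depth = nodes$depth[p] + 1L, stringsAsFactors = FALSE))
  }
  nodes$depth <- NULL
  nodes
}

.nodes_to_tree <- function(nodes, spacer = NA_character_) {
  t <- structure(list(nodes = nodes, spacer = spacer, source = NA_character_),
                 class = "glycan_tree")
  t$source <- write_glycan(t)
  t
}

#' Generate a random glycan library with planted motifs
#'
#' Backgrounds are random valid trees over a restricted alphabet (depth <= 5,
#' branching <= 3); planted members contain the requested motif by
#' construction (the motif tree, optionally decorated with a few extra
#' mannoses on its leaves). Emulates the composition of a printed mammalian
#' glycan array at desk scale.
#'
#' @param n Library size.
#' @param planted Character vector of motif glycan strings, one planted
#'   glycan per element (e.g.
#'   `rep("Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb", 10)`); `NULL` for none.
#' @param max_residues Largest background tree.
#' @param alphabet Residue alphabet for backgrounds.
#' @param decorate Maximum number of random mannoses appended to each
#'   planted motif.
#' @param seed Integer seed (generators are bit-reproducible given a seed).
#' @return List with `glycans` (tibble `glycan_id`, `structure`) and `truth`
#'   (tibble `glycan_id`, `planted`, `motif`).
#' @export
gen_glycan_library <- function(n, planted = NULL, max_residues = 10L,
                               alphabet = c("Man", "Gal", "Glc", "GlcNAc",
                                            "GalNAc", "Fuc", "Neu5Ac", "Xyl"),
                               decorate = 2L, seed = NULL) {
  stopifnot(n >= length(planted))
  .with_seed(seed, {
    spacers <- paste0("Sp", 0:25)
    structs <- character(n)
    is_planted <- rep(FALSE, n)
    motif <- rep(NA_character_, n)
    idx_planted <- if (length(planted)) seq_along(planted) else integer(0)
    for (i in seq_len(n)) {
      if (i %in% idx_planted) {
        tr <- parse_glycan(planted[i])
        extra <- if (decorate > 0) sample(0:decorate, 1) else 0L
        nodes <- tr$nodes
        for (k in seq_len(extra)) {
          leaves <- setdiff(nodes$id, nodes$parent)
          leaf <- if (length(leaves) == 1L) leaves else sample(leaves, 1)
          nodes <- rbind(nodes, data.frame(
            id = nrow(nodes) + 1L, name = "Man", anomer = "a",
            anomeric_carbon = 1L, parent = leaf,
            parent_pos = sample(2:6, 1), stringsAsFactors = FALSE))
        }
        tr <- .nodes_to_tree(nodes, spacer = sample(spacers, 1))
        structs[i] <- write_glycan(tr)
        is_planted[i] <- TRUE
        motif[i] <- planted[i]
      } else {
        n_res <- sample(1:max_residues, 1)
        nodes <- .random_tree_nodes(n_res, alphabet)
        structs[i] <- write_glycan(.nodes_to_tree(nodes,
                                                  spacer = sample(spacers, 1)))
      }
    }
    list(glycans = tibble::tibble(glycan_id = seq_len(n), structure = structs),
         truth = tibble::tibble(glycan_id = seq_len(n), planted = is_planted,
                                motif = motif))
  })
}

#' Generate replicate array RFUs for a glycan library
#'
#' Spot intensities are lognormal: background spots have log-mean
#' `baseline_log` plus an overall per-concentration intensity scale
#' `(concentration/max)^h` (the response exponent `h` models how total
#' signal tracks lectin concentration), and planted binders are additionally
#' `fold` times brighter at every concentration. Replicates are independent.
#'
#' @param library `glycans` tibble from [gen_glycan_library()].
#' @param binder_ids Glycan ids of the planted binders.
#' @param fold Binder/background intensity ratio (> 1).
#' @param concentrations Lectin concentrations (ug/ml).
#' @param reps Replicates per spot.
#' @param noise_sigma Lognormal sdlog of spot noise.
#' @param h Concentration-response exponent.
#' @param baseline_log Background log-mean intensity.
#' @param seed Integer seed.
#' @return List with `dataset` (long tibble `glycan_id`, `structure`,
#'   `concentration`, `replicate`, `rfu`) and `truth` (tibble of binder ids).
#' @export
gen_array_rfus <- function(library, binder_ids, fold = 20,
                           concentrations = c(10, 1, 0.1), reps = 6L,
                           noise_sigma = 0.3, h = 1,
                           baseline_log = log(100), seed = NULL) {
  stopifnot(fold > 1 || length(binder_ids) == 0, reps >= 1)
  .with_seed(seed, {
    cmax <- max(concentrations)
    grid <- expand.grid(glycan_id = library$glycan_id,
                        concentration = concentrations,
                        replicate = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
    scale_c <- (grid$concentration / cmax)^h
    is_b <- grid$glycan_id %in% binder_ids
    meanlog <- baseline_log + log(scale_c) + ifelse(is_b, log(fold), 0)
    grid$rfu <- rlnorm(nrow(grid), meanlog = meanlog, sdlog = noise_sigma)
    dataset <- tibble::as_tibble(grid) |>
      dplyr::left_join(library, by = "glycan_id") |>
      dplyr::relocate("structure", .after = "glycan_id") |>
      dplyr::arrange(.data$glycan_id, dplyr::desc(.data$concentration),
                     .data$replicate)
    list(dataset = dataset,
         truth = tibble::tibble(glycan_id = sort(binder_ids)))
  })
}

#' Generate a noisy one-site titration isotherm
#'
#' [simulate_isotherm()] plus additive Gaussian noise with SD equal to
#' `noise_frac` times the largest absolute heat.
#'
#' @param scheme A [titration_scheme()] (default: 18 injections).
#' @param params True [one_site_params()].
#' @param noise_frac Noise SD as a fraction of the peak heat.
#' @param seed Integer seed.
#' @return List with `isotherm` (tibble) and `truth` (the parameters).
#' @export
gen_isotherm <- function(scheme = titration_scheme(), params, noise_frac = 0.01,
                         seed = NULL) {
  .with_seed(seed, {
    iso <- simulate_isotherm(scheme, params)
    if (noise_frac > 0)
      iso$heat <- iso$heat + rnorm(nrow(iso), 0,
                                   noise_frac * max(abs(iso$heat)))
    list(isotherm = iso, truth = params)
  })
}

.plant_positions <- function(dom_start, dom_len, k, motif_len, offset,
                             max_tries = 1e4) {
  # non-overlapping starts; motif + downstream residue inside the domain
  span <- motif_len + offset
  for (try in seq_len(max_tries)) {
    starts <- sort(sample(dom_start:(dom_start + dom_len - span), k))
    # +2 keeps each site's leading residue clear of the previous site's
    # downstream position
    if (k < 2 || all(diff(starts) >= span + 2L)) return(starts)
  }
  stop("cannot pack ", k, " motifs into a domain of length ", dom_len,
       call. = FALSE)
}

#' Generate a lectin-like protein with planted CRS motifs
#'
#' Builds a two-domain bulb-lectin-like protein: random background residues
#' with the requested number of non-overlapping consensus sites planted per
#' domain and the requested residue written just downstream of each
#' (`"A"` for a mannose-type profile, `"Q"` for the substituted profile).
#' Planted sites satisfy the extended 10-mer consensus, so both
#' [scan_crs()] and [scan_extended()] find them. Backgrounds producing
#' accidental consensus matches are rejection-sampled away (capped at
#' `max_tries`).
#'
#' @param domain_lengths Lengths of the two (or more) domains.
#' @param crs_counts Planted motifs per domain (same length as
#'   `domain_lengths`).
#' @param downstream Residue written at `offset` past each planted 9-mer.
#' @param offset Downstream offset (residues).
#' @param nterm,linker,cterm Lengths of the flanking/linker segments.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap.
#' @return List with `record` (list `id`, `sequence`), `domains`
#'   ([domain_spans()]), and `truth` (tibble `domain`, `start` of each
#'   planted 9-mer, `downstream`).
#' @export
gen_lectin_seq <- function(domain_lengths = c(107L, 109L),
                           crs_counts = c(1L, 1L), downstream = "Q",
                           offset = 1L, nterm = 25L, linker = 13L, cterm = 3L,
                           seed = NULL, max_tries = 1e4) {
  stopifnot(length(domain_lengths) == length(crs_counts))
  aa <- names(.aa_residue_mass)
  bg_aa <- setdiff(aa, "Q")  # keep accidental consensus hits rare
  hyd <- default_hydrophobic()
  .with_seed(seed, {
    starts <- nterm + cumsum(c(1L, head(domain_lengths + linker, -1)))
    ends <- starts + domain_lengths - 1L
    total <- ends[length(ends)] + cterm
    for (try in seq_len(max_tries)) {
      s <- sample(bg_aa, total, replace = TRUE)
      truth <- list()
      for (d in seq_along(domain_lengths)) {
        k <- crs_counts[d]
        if (k == 0) next
        pos <- .plant_positions(starts[d] + 1L, domain_lengths[d] - 1L, k,
                                9L, offset)
        for (p in pos) {
          lead <- sample(c("M", "I", "L", "V"), 1)
          nine <- c("Q", sample(bg_aa, 1), "D", sample(bg_aa, 1), "N",
                    sample(hyd, 1), "V", sample(hyd, 1), "Y")
          s[p - 1L] <- lead
          s[p:(p + 8L)] <- nine
          s[p + 8L + offset] <- downstream
        }
        truth[[length(truth) + 1L]] <-
          tibble::tibble(domain = paste0("DOM", d), start = pos,
                         downstream = downstream)
      }
      seqstr <- paste(s, collapse = "")
      found <- scan_crs(seqstr)$start
      want <- if (length(truth)) sort(dplyr::bind_rows(truth)$start)
              else integer(0)
      if (identical(sort(found), as.integer(want))) {
        return(list(
          record = list(id = "synthetic_lectin", sequence = seqstr),
          domains = domain_spans(paste0("DOM", seq_along(domain_lengths)),
                                 starts, ends),
          truth = if (length(truth)) dplyr::bind_rows(truth)
                  else tibble::tibble(domain = character(), start = integer(),
                                      downstream = character())))
      }
    }
    stop("rejection sampling failed to produce a clean background",
         call. = FALSE)
  })
}

#' Generate an aligned protein family down a random tree
#'
#' Minimal i.i.d.-substitution simulator for exercising the distance and
#' tree stages: sites mutate independently along a random topology with
#' probability `1 - exp(-rate * branch length)`; optional columns are
#' gapped to exercise complete deletion.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param n_sites Alignment length.
#' @param rate Substitution rate per unit branch length.
#' @param gap_frac Fraction of columns receiving a gap in one random row.
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector) and `tree` (the
#'   generating `phylo`).
#' @export
gen_alignment <- function(n_taxa = 6L, n_sites = 200L, rate = 0.3,
                          gap_frac = 0, seed = NULL) {
  stopifnot(n_taxa >= 3, n_sites >= 1)
  aa <- names(.aa_residue_mass)
  .with_seed(seed, {
    tree <- ape::rtree(n_taxa)
    root_seq <- sample(aa, n_sites, replace = TRUE)
    n <- n_taxa
    seqs <- vector("list", n + tree$Nnode)
    seqs[[n + 1L]] <- root_seq
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
      s <- seqs[[p]]
      mut <- runif(n_sites) < 1 - exp(-rate * ord$edge.length[k])
      if (any(mut)) s[mut] <- sample(aa, sum(mut), replace = TRUE)
      seqs[[ch]] <- s
    }
    aln <- vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(aln) <- tree$tip.label
    if (gap_frac > 0) {
      cols <- sample(n_sites, max(1, round(gap_frac * n_sites)))
      for (cc in cols) {
        row <- sample(n, 1)
        substr(aln[row], cc, cc) <- "-"
      }
    }
    list(alignment = aln, tree = tree)
  })
}
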