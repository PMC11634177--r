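# Synthetic study generator.
#
# Downstream stages are exercised on generated data with known structure:
# random tree-shaped molecules over the 14-element vocabulary, a scale-free
# PPI network, and perturbation tables in which the log fold change of a
# gene under a drug is an additive function of planted chemical-element
# effects plus Gaussian noise. One generator call produces one synthetic
# "cell line"; families of cell lines are built by repeated calls with
# different planted effects over a shared molecule set.

#' A planted chemical-element effect
#'
#' Declares that molecules containing `element` shift the logFC of every
#' gene in `target_genes` by `direction * beta`.
#'
#' @param element Element symbol from [atom_vocabulary()].
#' @param target_genes Non-empty character vector of gene ids.
#' @param beta Positive effect size in logFC units.
#' @param direction `+1` (up-regulation) or `-1` (down-regulation).
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(element, target_genes, beta, direction = 1) {
  if (!(element %in% atom_vocabulary())) {
    stop("planted-effect element '", element, "' is not in the vocabulary")
  }
  if (length(target_genes) == 0L) stop("target_genes must be non-empty")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!(direction %in% c(1, -1))) stop("direction must be +1 or -1")
  structure(list(element = element, target_genes = as.character(target_genes),
                 beta = beta, direction = direction),
            class = "planted_effect")
}

# default per-molecule element inclusion probabilities: a carbon skeleton
# with common heteroatoms, occasional halogens, and rare metals/metalloids
.default_prevalence <- c(
  C = 1.00, N = 0.60, O = 0.70, Cl = 0.20, Ca = 0.02, S = 0.30, F = 0.20,
  Br = 0.10, I = 0.05, P = 0.10, Au = 0.01, B = 0.05, Si = 0.03, Hg = 0.01
)

#' Configuration of a synthetic study
#'
#' @param n_drugs Number of molecules.
#' @param n_genes Number of landmark genes (`g0001`, `g0002`, ...).
#' @param element_prevalence Named vector of per-molecule inclusion
#'   probabilities (names from [atom_vocabulary()], values in `[0,1]`).
#'   Unnamed elements keep the package defaults.
#' @param noise_sd Gaussian noise standard deviation in logFC units.
#' @param effects List of [planted_effect()] objects.
#' @param seed Integer RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 200, n_genes = 100,
                         element_prevalence = NULL, noise_sd = 0.3,
                         effects = list(), seed = 42) {
  prev <- .default_prevalence
  if (!is.null(element_prevalence)) {
    if (is.null(names(element_prevalence)) ||
        any(!nzchar(names(element_prevalence)))) {
      stop("element_prevalence must be a named vector")
    }
    bad <- setdiff(names(element_prevalence), atom_vocabulary())
    if (length(bad) > 0L) {
      stop("element_prevalence names outside the vocabulary: ",
           paste(bad, collapse = ", "))
    }
    if (any(element_prevalence < 0 | element_prevalence > 1)) {
      stop("element_prevalence probabilities must lie in [0, 1]")
    }
    prev[names(element_prevalence)] <- element_prevalence
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  for (e in effects) {
    if (!inherits(e, "planted_effect")) stop("effects must be planted_effect objects")
    gi <- suppressWarnings(as.integer(sub("^g", "", e$target_genes)))
    if (any(!is.na(gi) & gi > n_genes)) {
      stop("effect targets genes beyond n_genes")
    }
  }
  structure(list(n_drugs = n_drugs, n_genes = n_genes,
                 element_prevalence = prev, noise_sd = noise_sd,
                 effects = effects, seed = as.integer(seed)),
            class = "synth_config")
}

#' Gene id labels of a synthetic study
#' @param n_genes Number of genes.
#' @return Character vector `g0001 ... g<n>`.
#' @export
synth_gene_ids <- function(n_genes) sprintf("g%04d", seq_len(n_genes))

# Build one random valence-respecting molecule as a tree with an optional
# single ring closure, then emit its SMILES. Returns a molecular_graph.
.random_molecule <- function(prev, min_atoms = 6L, max_atoms = 16L,
                             ring_prob = 0.3) {
  present <- names(prev)[stats::runif(length(prev)) < prev]
  if (length(present) == 0L) present <- "C"
  # one or two atoms of each included heteroatom, carbon fills the rest
  counts <- stats::setNames(rep(0L, length(atom_vocabulary())), atom_vocabulary())
  for (el in present) counts[el] <- 1L + stats::rbinom(1L, 1L, 0.4)
  n_target <- sample(min_atoms:max_atoms, 1L)
  if (sum(counts) < n_target) counts["C"] <- counts["C"] + (n_target - sum(counts))
  elements <- rep(names(counts), counts)
  # attach high-valence atoms first so monovalent atoms never strand the tree
  elements <- elements[order(-.element_valence[elements],
                             stats::runif(length(elements)))]
  n <- length(elements)
  cap <- .element_valence[elements]
  free <- cap
  edges <- matrix(integer(), 0, 2)
  for (k in seq_len(n)[-1]) {
    open <- which(free[seq_len(k - 1L)] > 0L)
    if (length(open) == 0L) break  # remaining atoms dropped (rare)
    a <- open[sample.int(length(open), 1L)]
    edges <- rbind(edges, c(a, k))
    free[a] <- free[a] - 1L
    free[k] <- free[k] - 1L
  }
  used <- sort(unique(c(1L, as.vector(edges))))
  if (length(used) < n) {
    remap <- match(seq_len(n), used)
    keep <- !is.na(remap[edges[, 1]]) & !is.na(remap[edges[, 2]])
    edges <- matrix(remap[edges[keep, , drop = FALSE]], ncol = 2)
    elements <- elements[used]
    free <- free[used]
    n <- length(elements)
  }
  if (n >= 4L && stats::runif(1) < ring_prob) {
    openv <- which(free > 0L)
    if (length(openv) >= 2L) {
      adjacent <- matrix(FALSE, n, n)
      if (nrow(edges) > 0L) {
        adjacent[edges] <- TRUE
        adjacent[edges[, 2:1, drop = FALSE]] <- TRUE
      }
      cand <- which(outer(openv, openv, "<"), arr.ind = TRUE)
      pairs <- cbind(openv[cand[, 1]], openv[cand[, 2]])
      ok <- !adjacent[pairs]
      if (any(ok)) {
        pick <- which(ok)[sample.int(sum(ok), 1L)]
        edges <- rbind(edges, pairs[pick, ])
      }
    }
  }
  g <- molecular_graph(elements, edges)
  g$smiles <- write_smiles(g)
  g
}

#' Generate random molecules
#'
#' Molecules are random valence-respecting trees with an optional single
#' ring closure; element composition follows the per-molecule inclusion
#' probabilities in `config$element_prevalence`.
#'
#' @param n Number of molecules (`n = 0` gives an empty result).
#' @param config A [synth_config()]; its `seed` makes the output
#'   deterministic.
#' @return A data.frame with columns `drug_id`, `smiles`, and a list column
#'   `graph` of [molecular_graph()] objects.
#' @export
generate_molecules <- function(n, config = synth_config()) {
  stopifnot(inherits(config, "synth_config"), n >= 0)
  if (n == 0L) {
    out <- data.frame(drug_id = character(), smiles = character())
    out$graph <- list()
    return(out)
  }
  set.seed(config$seed)
  graphs <- lapply(seq_len(n), function(i) .random_molecule(config$element_prevalence))
  out <- data.frame(
    drug_id = sprintf("d%04d", seq_len(n)),
    smiles = vapply(graphs, function(g) g$smiles, character(1))
  )
  out$graph <- graphs
  out
}

#' Generate a synthetic PPI network
#'
#' Undirected, simple, connected scale-free graph grown by preferential
#' attachment (each incoming node attaches `round(mean_degree / 2)` edges,
#' so the realized mean degree approaches `mean_degree`).
#'
#' @param n_genes Number of genes (>= 2); ids are `g0001 ...`.
#' @param mean_degree Desired mean degree (>= 1).
#' @param seed Integer RNG seed.
#' @return A data.frame edge list with columns `gene_a`, `gene_b`.
#' @export
generate_ppi <- function(n_genes, mean_degree = 6, seed = 1) {
  if (n_genes < 2) stop("n_genes must be at least 2")
  if (mean_degree < 1) stop("mean_degree must be at least 1")
  m <- max(1L, as.integer(round(mean_degree / 2)))
  set.seed(seed)
  g <- igraph::sample_pa(n_genes, power = 1, m = m, directed = FALSE,
                         algorithm = "psumtree")
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- synth_gene_ids(n_genes)
  data.frame(gene_a = ids[pmin(el[, 1], el[, 2])],
             gene_b = ids[pmax(el[, 1], el[, 2])])
}

#' Generate a planted-effect perturbation table
#'
#' For drug d and gene g,
#' `logFC(d,g) = sum_e direction_e * beta_e * contains(d, element_e) *
#' targets(e, g) + N(0, noise_sd^2)`. One record per (drug, gene); a single
#' synthetic cell line per call.
#'
#' @param molecules Output of [generate_molecules()].
#' @param n_genes Number of genes.
#' @param effects List of [planted_effect()] objects.
#' @param noise_sd Gaussian noise sd (logFC units).
#' @param seed Integer RNG seed.
#' @param cell_line Cell-line label stamped on every record.
#' @return A data.frame with columns `drug_id`, `smiles`, `cell_line`,
#'   `gene_id`, `logFC` (`n_drugs * n_genes` rows).
#' @export
generate_perturbations <- function(molecules, n_genes, effects = list(),
                                   noise_sd = 0.3, seed = 42,
                                   cell_line = "SYN1") {
  for (e in effects) {
    if (!inherits(e, "planted_effect")) stop("effects must be planted_effect objects")
  }
  n_drugs <- nrow(molecules)
  gene_ids <- synth_gene_ids(n_genes)
  lfc <- matrix(0, n_drugs, n_genes, dimnames = list(molecules$drug_id, gene_ids))
  for (e in effects) {
    has <- vapply(molecules$graph, function(g) e$element %in% g$elements,
                  logical(1))
    tg <- match(e$target_genes, gene_ids)
    if (anyNA(tg)) stop("effect target gene outside g0001..g", sprintf("%04d", n_genes))
    lfc[has, tg] <- lfc[has, tg] + e$direction * e$beta
  }
  set.seed(seed)
  if (noise_sd > 0) {
    lfc <- lfc + matrix(stats::rnorm(n_drugs * n_genes, sd = noise_sd),
                        n_drugs, n_genes)
  }
  data.frame(
    drug_id = rep(molecules$drug_id, each = n_genes),
    smiles = rep(molecules$smiles, each = n_genes),
    cell_line = cell_line,
    gene_id = rep(gene_ids, times = n_drugs),
    logFC = as.vector(t(lfc))
  )
}

#' The package's parameter-recovery study conditions
#'
#' The fixed synthetic configuration used by the bundled benchmark: 200
#' drugs, 100 genes, one planted effect (sulfur up-regulates genes
#' g0001-g0020 with beta = 2.5), noise sd 0.3, seed 42.
#'
#' @return A [synth_config()].
#' @export
benchmark_synth_config <- function() {
  synth_config(
    n_drugs = 200, n_genes = 100, noise_sd = 0.3, seed = 42,
    effects = list(planted_effect("S", synth_gene_ids(20), beta = 2.5,
                                  direction = 1))
  )
}
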