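# Molecular graphs over a fixed 14-element vocabulary.
#
# Drugs are represented as undirected, untyped heavy-atom graphs: atoms are
# nodes, covalent bonds are edges, hydrogens are implicit and dropped. The
# element vocabulary is fixed to the 14 elements that dominate screening
# libraries; the position of an element in `atom_vocabulary()` is its one-hot
# index everywhere in the package.

#' The fixed 14-element atom vocabulary
#'
#' Ordered element symbols; the one-hot index of an element is its position
#' in this vector (C = 1, ..., Hg = 14). All molecular graphs handled by the
#' package must use elements from this set.
#'
#' @return Character vector of 14 element symbols.
#' @export
atom_vocabulary <- function() {
  c("C", "N", "O", "Cl", "Ca", "S", "F", "Br", "I", "P", "Au", "B", "Si", "Hg")
}

# simple valence caps used by the molecule generator (bond slots per atom)
.element_valence <- c(
  C = 4L, N = 3L, O = 2L, Cl = 1L, Ca = 2L, S = 2L, F = 1L, Br = 1L,
  I = 1L, P = 4L, Au = 1L, B = 3L, Si = 4L, Hg = 1L
)

# elements writable without brackets in SMILES (organic subset, within vocab)
.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Construct a molecular graph
#'
#' @param elements Character vector of element symbols (vocabulary only).
#' @param edges Two-column integer matrix of undirected bonds (may have zero
#'   rows for a single-atom molecule).
#' @param smiles Optional source SMILES string.
#' @return An object of class `molecular_graph` with fields `elements`,
#'   `edges` (each row stored with the smaller index first) and `smiles`.
#' @export
molecular_graph <- function(elements, edges = matrix(integer(), 0, 2),
                            smiles = NA_character_) {
  elements <- as.character(elements)
  if (length(elements) == 0L) stop("molecular graph must have at least one atom")
  bad <- setdiff(unique(elements), atom_vocabulary())
  if (length(bad) > 0L) {
    stop("element(s) outside the 14-element vocabulary: ",
         paste(bad, collapse = ", "))
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > length(elements))) {
      stop("edge endpoint out of range")
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loop bonds are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(edges)) stop("duplicate bonds are not allowed")
  }
  g <- structure(
    list(elements = elements, edges = edges, smiles = smiles),
    class = "molecular_graph"
  )
  if (!.graph_connected(g)) stop("molecular graph must be connected")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d atoms, %d bonds", length(x$elements),
              nrow(x$edges)))
  if (!is.na(x$smiles)) cat("  ", x$smiles)
  cat("\n")
  invisible(x)
}

.graph_connected <- function(g) {
  n <- length(g$elements)
  if (n == 1L) return(TRUE)
  adj <- .adjacency_list(n, g$edges)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

.adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the subset of SMILES needed for screening libraries over the
#' 14-element vocabulary: organic-subset atoms, bracket atoms (isotope,
#' charge, chirality and explicit-H annotations are accepted and ignored),
#' aromatic lowercase atoms, branches, ring-bond closures (including `%nn`)
#' and bond symbols (bond order is discarded; bonds become plain edges).
#' Hydrogens are implicit and never appear as nodes. Multi-fragment SMILES
#' (`.`) are rejected because graphs must be connected.
#'
#' @param smiles A single SMILES string.
#' @return A [molecular_graph()].
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L) {
    stop("SMILES must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elements <- character()
  edges <- matrix(integer(), 0, 2)
  prev <- NA_integer_         # atom a new atom bonds to
  branch_stack <- integer()
  ring_open <- list()         # ring digit -> atom index
  i <- 1L
  perr <- function(msg) stop(sprintf("cannot parse SMILES '%s': %s", smiles, msg))

  add_atom <- function(sym) {
    if (!(sym %in% atom_vocabulary())) {
      stop(sprintf("SMILES '%s' contains element '%s' outside the 14-element vocabulary",
                   smiles, sym))
    }
    elements[length(elements) + 1L] <<- sym
    idx <- length(elements)
    if (!is.na(prev)) edges <<- rbind(edges, c(prev, idx))
    prev <<- idx
    idx
  }
  close_ring <- function(key) {
    if (is.na(prev)) perr("ring bond before any atom")
    if (!is.null(ring_open[[key]])) {
      other <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      if (other == prev) perr("ring bond to the same atom")
      edges <<- rbind(edges, c(other, prev))
    } else {
      ring_open[[key]] <<- prev
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) perr("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- sub("^[0-9]+", "", body)                    # isotope
      m <- regmatches(body, regexpr("^([A-Z][a-z]?|[a-z])", body))
      if (length(m) == 0L) perr(sprintf("bad bracket atom [%s]", body))
      sym <- m
      rest <- substr(body, nchar(sym) + 1L, nchar(body))
      if (grepl("[^@H0-9+\\-]", rest)) perr(sprintf("bad bracket atom [%s]", body))
      if (sym %in% letters || sym %in% c("cl", "br")) {
        sym <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      }
      add_atom(sym)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      i <- i + 1L                                          # bond order dropped
    } else if (ch == "(") {
      if (is.na(prev)) perr("branch before any atom")
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L) perr("unmatched ')'")
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) perr("truncated %nn ring bond")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == ".") {
      perr("multi-fragment SMILES are not supported (graphs must be connected)")
    } else {
      # organic subset, two-character symbols first
      sym <- NULL
      if (i < n) {
        two <- paste0(ch, chars[i + 1L])
        if (two %in% c("Cl", "Br")) { sym <- two; i <- i + 2L }
      }
      if (is.null(sym)) {
        if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
          sym <- ch; i <- i + 1L
        } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
          sym <- toupper(ch); i <- i + 1L
        } else {
          perr(sprintf("unexpected character '%s' at position %d", ch, i))
        }
      }
      add_atom(sym)
    }
  }
  if (length(branch_stack) > 0L) perr("unmatched '('")
  if (length(ring_open) > 0L) perr("unmatched ring bond")
  if (length(elements) == 0L) perr("no atoms")
  molecular_graph(elements, edges, smiles = smiles)
}

#' Write a molecular graph as a SMILES string
#'
#' Emits single bonds only (the package's graphs are untyped); ring bonds
#' (non-spanning-tree edges) become numeric ring closures. Elements outside
#' the SMILES organic subset are written in brackets.
#'
#' @param graph A [molecular_graph()].
#' @return A SMILES string that parses back to an isomorphic graph.
#' @export
write_smiles <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- length(graph$elements)
  adj <- .adjacency_list(n, graph$edges)
  # DFS spanning tree from atom 1; leftover edges are ring closures
  parent <- rep(NA_integer_, n)
  order_visited <- integer(0)
  seen <- logical(n)
  stack <- 1L; seen[1L] <- TRUE
  children <- vector("list", n)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_visited <- c(order_visited, v)
    for (w in sort(adj[[v]])) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        children[[v]] <- c(children[[v]], w)
        stack <- c(stack, w)
      }
    }
  }
  tree_edge <- matrix(c(which(!is.na(parent)), parent[!is.na(parent)]),
                      ncol = 2)
  tree_key <- paste(pmin(tree_edge[, 1], tree_edge[, 2]),
                    pmax(tree_edge[, 1], tree_edge[, 2]))
  all_key <- paste(graph$edges[, 1], graph$edges[, 2])
  ring_edges <- graph$edges[!(all_key %in% tree_key), , drop = FALSE]
  ring_marks <- vector("list", n)
  if (nrow(ring_edges) > 0L) {
    for (k in seq_len(nrow(ring_edges))) {
      ring_marks[[ring_edges[k, 1]]] <- c(ring_marks[[ring_edges[k, 1]]], k)
      ring_marks[[ring_edges[k, 2]]] <- c(ring_marks[[ring_edges[k, 2]]], k)
    }
  }
  atom_token <- function(v) {
    sym <- graph$elements[v]
    tok <- if (sym %in% .organic_subset) sym else paste0("[", sym, "]")
    digs <- ring_marks[[v]]
    if (!is.null(digs)) {
      tok <- paste0(tok, paste0(ifelse(digs < 10, as.character(digs),
                                       sprintf("%%%02d", digs)), collapse = ""))
    }
    tok
  }
  emit <- function(v) {
    out <- atom_token(v)
    kids <- children[[v]]
    if (length(kids) > 0L) {
      for (k in seq_along(kids)) {
        sub <- emit(kids[k])
        out <- if (k < length(kids)) paste0(out, "(", sub, ")")
               else paste0(out, sub)
      }
    }
    out
  }
  emit(1L)
}

#' One-hot encode the atoms of a molecular graph
#'
#' @param graph A [molecular_graph()].
#' @return An `n_atoms x 14` binary matrix; column order follows
#'   [atom_vocabulary()], and every row sums to exactly 1.
#' @export
one_hot_atoms <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  vocab <- atom_vocabulary()
  idx <- match(graph$elements, vocab)
  m <- matrix(0, nrow = length(idx), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Test whether two molecular graphs are isomorphic
#'
#' Element-labelled graph isomorphism, delegated to igraph's VF2 matcher.
#'
#' @param g1,g2 [molecular_graph()] objects.
#' @return Logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (length(g1$elements) != length(g2$elements)) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  mk <- function(g) {
    ig <- igraph::make_empty_graph(n = length(g$elements), directed = FALSE)
    if (nrow(g$edges) > 0L) ig <- igraph::add_edges(ig, t(g$edges))
    ig
  }
  col <- function(g) match(g$elements, atom_vocabulary())
  igraph::isomorphic(mk(g1), mk(g2), method = "vf2",
                     vertex.color1 = col(g1), vertex.color2 = col(g2))
}

#' Read a .smi drug library
#'
#' One molecule per line: `SMILES<TAB>drug_id`. Lines starting with `#` and
#' blank lines are skipped. Missing ids are filled with `mol<line>`.
#'
#' @param path File path.
#' @return A data.frame with columns `drug_id` and `smiles`.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(drug_id = character(), smiles = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2] else sprintf("mol%d", i)
  }, character(1))
  data.frame(drug_id = ids, smiles = smiles)
}

#' Write a .smi drug library
#'
#' @param drugs Data.frame with columns `drug_id` and `smiles`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(drugs, path) {
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)))
  writeLines(paste(drugs$smiles, drugs$drug_id, sep = "\t"), path)
  invisible(path)
}
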