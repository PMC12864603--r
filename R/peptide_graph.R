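# Molecular view: deterministic linear-peptide SMILES and graph featurization.
#
# Each residue contributes a backbone unit N-CA-C(=O) plus its side chain;
# units are condensed N-terminus to C-terminus and the chain ends with the
# free carboxylic acid oxygen. No stereochemistry is emitted: the downstream
# featurization is strictly 2D topology. Canonicalization (and with it
# aromaticity notation) is delegated to OpenBabel, invoked as one batched
# `obabel` process because the per-call overhead of the in-process bindings
# is prohibitive for datasets of hundreds of peptides; the canonical SMILES
# is then parsed by a small exact reader covering the organic-subset grammar.
#
# The node/edge feature sets are a documented reconstruction (the choice of
# features is not fixed by the model family): per heavy atom
#   [element one-hot {C,N,O,S,other}, degree one-hot 1..4, formal charge,
#    aromatic flag, implicit-H count, in-ring flag]            (13 values)
# and per bond
#   [order one-hot {single, double, aromatic}, conjugated flag, in-ring flag]
#                                                              (5 values)

#' Feature-layout version of the graph featurizer
#'
#' Caches and checkpoints record this string; mixing artifacts across
#' featurizer versions raises an error.
#' @export
FEATURIZER_VERSION <- "aopred-graph-v1"

NODE_FEATURE_DIM <- 13L
EDGE_FEATURE_DIM <- 5L

# Side-chain SMILES fragments attached at the alpha carbon. Glycine has no
# side chain; proline's backbone nitrogen sits inside the pyrrolidine ring.
RESIDUE_SIDE_CHAINS <- c(
  A = "C",
  R = "CCCNC(=N)N",
  N = "CC(N)=O",
  D = "CC(O)=O",
  C = "CS",
  E = "CCC(O)=O",
  Q = "CCC(N)=O",
  G = "",
  H = "Cc1c[nH]cn1",
  I = "C(C)CC",
  L = "CC(C)C",
  K = "CCCCN",
  M = "CCSC",
  F = "Cc1ccccc1",
  P = "",
  S = "CO",
  T = "C(C)O",
  W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1",
  V = "C(C)C"
)

residue_unit <- function(code) {
  if (code == "G") return("NCC(=O)")
  if (code == "P") return("N1CCCC1C(=O)")
  paste0("NC(", RESIDUE_SIDE_CHAINS[[code]], ")C(=O)")
}

#' Build the SMILES strings of linear peptides
#'
#' Condenses residue units N-terminus to C-terminus (free amine at the N
#' terminus, free carboxylic acid at the C terminus), with no stereochemistry.
#' The result is canonicalized with OpenBabel so that identical molecules
#' always yield identical strings.
#'
#' @param sequence A character vector of validated peptide sequences.
#' @param canonical Canonicalize the assembled SMILES (recommended).
#' @return A character vector of SMILES strings, one per sequence.
#' @export
#' @examples
#' peptide_to_smiles("GG", canonical = FALSE)
peptide_to_smiles <- function(sequence, canonical = TRUE) {
  raw <- vapply(toupper(sequence), function(s) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) == 0 || !all(ch %in% AA_ALPHABET)) {
      stop_aopred(paste0("Non-standard residues in '", s, "'."),
                  "aopred_validation_error")
    }
    paste0(paste(vapply(ch, residue_unit, character(1)), collapse = ""), "O")
  }, character(1), USE.NAMES = FALSE)
  if (!canonical) return(raw)
  canonical_smiles(raw)
}

find_obabel <- function() {
  path <- Sys.which("obabel")
  if (nzchar(path)) return(unname(path))
  NULL
}

# Batch-canonicalize; returns NA for strings OpenBabel cannot parse.
canonicalize_batch <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  obabel <- find_obabel()
  if (is.null(obabel)) {
    if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
      stop_aopred("Canonicalization needs the obabel binary or ChemmineOB.",
                  "aopred_config_error")
    }
    # slow in-process fallback, one call per molecule
    return(vapply(smiles, function(s) {
      out <- tryCatch(
        ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
        error = function(e) ""
      )
      out <- strsplit(out, "[\t\n]")[[1]][1]
      if (is.na(out) || !nzchar(out)) NA_character_ else out
    }, character(1), USE.NAMES = FALSE))
  }
  # titles carry the input index so skipped molecules are detectable
  input <- paste0(smiles, " idx", seq_along(smiles))
  out <- suppressWarnings(
    system2(obabel, c("-ismi", "-ocan"), input = input,
            stdout = TRUE, stderr = FALSE)
  )
  res <- rep(NA_character_, length(smiles))
  parts <- strsplit(out, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2 && grepl("^idx\\d+", p[2])) {
      i <- as.integer(sub("^idx(\\d+).*$", "\\1", p[2]))
      if (!is.na(i) && nzchar(p[1])) res[i] <- p[1]
    }
  }
  res
}

#' Canonicalize SMILES strings
#'
#' @param smiles A character vector of SMILES strings.
#' @return The OpenBabel-canonical forms.
#' @export
canonical_smiles <- function(smiles) {
  out <- canonicalize_batch(smiles)
  if (anyNA(out)) {
    stop_aopred(
      paste0("SMILES canonicalization failed for: ",
             paste(smiles[is.na(out)], collapse = ", ")),
      "aopred_smiles_error"
    )
  }
  out
}

## ---------------------------------------------------------------------------
## SMILES reader (organic-subset grammar: bracket atoms, branches, ring
## closures incl. %nn, bond symbols - = # : , aromatic lowercase atoms)

DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

parse_smiles <- function(smiles) {
  fail <- function(why) {
    stop_aopred(paste0("SMILES could not be parsed: '", smiles, "' (", why, ")"),
                "aopred_smiles_error", smiles = smiles)
  }
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    fail("empty input")
  }
  n <- nchar(smiles)
  elem <- character(0); arom <- logical(0); chg <- numeric(0); hexp <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bord <- character(0) # "", "-", "=", "#", ":"
  prev <- 0L
  pending <- ""
  stack <- integer(0)
  ring <- list() # open ring closures: id -> c(atom, bond symbol)
  i <- 1L
  add_bond <- function(a, b, sym) {
    b1 <<- c(b1, a); b2 <<- c(b2, b); bord <<- c(bord, sym)
  }
  new_atom <- function(el, ar, charge, h) {
    elem <<- c(elem, el); arom <<- c(arom, ar)
    chg <<- c(chg, charge); hexp <<- c(hexp, h)
    id <- length(elem)
    if (prev > 0L) add_bond(prev, id, pending)
    prev <<- id
    pending <<- ""
  }
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "(") {
      if (prev == 0L) fail("branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) fail("unbalanced parentheses")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == ".") {
      fail("disconnected components are unsupported")
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        id <- substr(smiles, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", id)) fail("bad %nn ring closure")
        i <- i + 3L
      } else {
        id <- ch
        i <- i + 1L
      }
      if (prev == 0L) fail("ring closure before any atom")
      open <- ring[[id]]
      if (is.null(open)) {
        ring[[id]] <- list(atom = prev, sym = pending)
        pending <- ""
      } else {
        sym <- if (nzchar(pending)) pending else open$sym
        if (nzchar(open$sym) && nzchar(pending) && open$sym != pending) {
          fail("conflicting ring-closure bond symbols")
        }
        if (open$atom == prev) fail("self-bond ring closure")
        add_bond(open$atom, prev, sym)
        ring[[id]] <- NULL
        pending <- ""
      }
    } else if (ch == "[") {
      close <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (close < 0) fail("unterminated bracket atom")
      body <- substr(smiles, i + 1L, i + close - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$",
        body
      ))[[1]]
      if (length(m) == 0) fail(paste0("bad bracket atom [", body, "]"))
      sym <- m[3]
      ar <- sym == tolower(sym) && sym != "*"
      el <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      h <- if (nzchar(m[5])) {
        if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
      } else 0L
      charge <- 0
      if (nzchar(m[6])) {
        cs <- m[6]
        charge <- if (grepl("^\\++$", cs)) nchar(cs)
          else if (grepl("^-+$", cs)) -nchar(cs)
          else if (cs == "+") 1
          else if (cs == "-") -1
          else as.numeric(cs)
      }
      new_atom(el, ar, charge, h)
      i <- i + close
    } else {
      two <- substr(smiles, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        new_atom(two, FALSE, 0, NA_integer_)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        new_atom(ch, FALSE, 0, NA_integer_)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        new_atom(toupper(ch), TRUE, 0, NA_integer_)
        i <- i + 1L
      } else {
        fail(paste0("unexpected character '", ch, "' at position ", i))
      }
    }
  }
  if (length(stack)) fail("unbalanced parentheses")
  if (length(ring)) fail("unclosed ring bond")
  if (length(elem) == 0) fail("no atoms")
  list(elem = elem, aromatic = arom, charge = chg, h_explicit = hexp,
       b1 = b1, b2 = b2, bond_sym = bord)
}

# Edges lying on any cycle (= non-bridges), via fundamental cycles of a BFS
# spanning tree. Returns a logical vector over edges.
ring_bonds <- function(n_atoms, b1, b2) {
  n_bonds <- length(b1)
  on_ring <- logical(n_bonds)
  if (n_bonds == 0) return(on_ring)
  adj <- vector("list", n_atoms)
  for (i in seq_len(n_bonds)) {
    adj[[b1[i]]] <- c(adj[[b1[i]]], i)
    adj[[b2[i]]] <- c(adj[[b2[i]]], i)
  }
  parent_edge <- integer(n_atoms); depth <- rep(-1L, n_atoms)
  parent <- integer(n_atoms)
  tree_edge <- logical(n_bonds)
  nontree <- integer(0)
  for (root in seq_len(n_atoms)) {
    if (depth[root] >= 0) next
    depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (ei in adj[[v]]) {
        u <- if (b1[ei] == v) b2[ei] else b1[ei]
        if (depth[u] < 0) {
          depth[u] <- depth[v] + 1L
          parent[u] <- v
          parent_edge[u] <- ei
          tree_edge[ei] <- TRUE
          queue <- c(queue, u)
        } else if (!tree_edge[ei] && !(ei %in% nontree)) {
          nontree <- c(nontree, ei)
        }
      }
    }
  }
  for (ei in nontree) {
    on_ring[ei] <- TRUE
    u <- b1[ei]; v <- b2[ei]
    while (u != v) { # walk both endpoints up to their lowest common ancestor
      if (depth[u] < depth[v]) { t <- u; u <- v; v <- t }
      on_ring[parent_edge[u]] <- TRUE
      u <- parent[u]
    }
  }
  on_ring
}

#' Convert a SMILES string into an attributed molecular graph
#'
#' Heavy atoms only; hydrogens are implicit and carried as a per-atom count
#' feature. See the package vignette for the exact feature layout (it is a
#' reconstruction, versioned as [FEATURIZER_VERSION]).
#'
#' @param smiles A parseable SMILES string (organic-subset grammar; aromatic
#'   rings in lowercase notation as produced by [canonical_smiles()]).
#' @return An object of class `mol_graph`: list with `node_features`
#'   (`n_atoms x 13`), `edges` (`n_bonds x 2`, undirected), `edge_features`
#'   (`n_bonds x 5`), `n_atoms`, `n_bonds`, `version`.
#' @export
#' @examples
#' smiles_to_graph("NCC(=O)O") # glycine
smiles_to_graph <- function(smiles) {
  p <- parse_smiles(smiles)
  n_atoms <- length(p$elem)
  n_bonds <- length(p$b1)
  edges <- cbind(p$b1, p$b2)
  in_ring_bond <- ring_bonds(n_atoms, p$b1, p$b2)

  # an unannotated bond between two aromatic atoms is aromatic only inside a
  # ring (a plain single bond joins e.g. two separate aromatic rings)
  bond_aromatic <- logical(n_bonds)
  order <- numeric(n_bonds)
  for (i in seq_len(n_bonds)) {
    sym <- p$bond_sym[i]
    both_ar <- p$aromatic[p$b1[i]] && p$aromatic[p$b2[i]]
    if (sym == ":" || (sym == "" && both_ar && in_ring_bond[i])) {
      bond_aromatic[i] <- TRUE
      order[i] <- 1.5
    } else {
      order[i] <- switch(sym, "=" = 2, "#" = 3, 1)
    }
  }

  degree <- tabulate(c(p$b1, p$b2), nbins = n_atoms)
  bond_order_sum <- numeric(n_atoms)
  for (i in seq_len(n_bonds)) {
    bond_order_sum[edges[i, ]] <- bond_order_sum[edges[i, ]] + order[i]
  }
  implicit_h <- integer(n_atoms)
  for (a in seq_len(n_atoms)) {
    if (!is.na(p$h_explicit[a])) {
      implicit_h[a] <- p$h_explicit[a] # bracket atoms state their H count
    } else {
      vals <- DEFAULT_VALENCES[[p$elem[a]]]
      if (is.null(vals)) {
        implicit_h[a] <- 0L
      } else {
        need <- ceiling(bond_order_sum[a]) - p$charge[a]
        v <- vals[vals >= need]
        implicit_h[a] <- if (length(v)) as.integer(v[1] - need) else 0L
      }
    }
  }

  aromatic_atom <- p$aromatic
  for (i in which(bond_aromatic)) aromatic_atom[edges[i, ]] <- TRUE
  in_ring_atom <- logical(n_atoms)
  for (i in which(in_ring_bond)) in_ring_atom[edges[i, ]] <- TRUE

  # conjugation: aromatic bonds, or bonds bridging unsaturation (amide C-N,
  # carboxyl C-O and the like)
  has_multiple <- logical(n_atoms)
  for (i in seq_len(n_bonds)) {
    if (order[i] >= 2 || bond_aromatic[i]) has_multiple[edges[i, ]] <- TRUE
  }
  bond_conjugated <- vapply(seq_len(n_bonds), function(i) {
    u <- edges[i, 1]
    v <- edges[i, 2]
    bond_aromatic[i] ||
      (has_multiple[u] && has_multiple[v]) ||
      (has_multiple[u] && p$elem[v] %in% c("N", "O", "S")) ||
      (has_multiple[v] && p$elem[u] %in% c("N", "O", "S"))
  }, logical(1))

  elem_levels <- c("C", "N", "O", "S")
  node_features <- cbind(
    outer(p$elem, elem_levels, "==") * 1,
    as.numeric(!p$elem %in% elem_levels),
    outer(pmin(degree, 4L), 1:4, "==") * 1,
    p$charge,
    as.numeric(aromatic_atom),
    as.numeric(implicit_h),
    as.numeric(in_ring_atom)
  )
  colnames(node_features) <- c(
    "elem_C", "elem_N", "elem_O", "elem_S", "elem_other",
    "deg_1", "deg_2", "deg_3", "deg_4",
    "charge", "aromatic", "implicit_h", "in_ring"
  )
  edge_features <- cbind(
    single = as.numeric(!bond_aromatic & order <= 1),
    double = as.numeric(!bond_aromatic & order >= 2),
    aromatic = as.numeric(bond_aromatic),
    conjugated = as.numeric(bond_conjugated),
    in_ring = as.numeric(in_ring_bond)
  )
  dimnames(edges) <- NULL
  structure(
    list(
      node_features = node_features, edges = edges,
      edge_features = edge_features, n_atoms = as.integer(n_atoms),
      n_bonds = as.integer(n_bonds), version = FEATURIZER_VERSION
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$n_atoms, " atoms, ", x$n_bonds, " bonds (",
      x$version, ")\n", sep = "")
  invisible(x)
}

#' Is a molecular graph connected?
#'
#' @param graph A `mol_graph`.
#' @return `TRUE` if all atoms are reachable from atom 1.
#' @export
graph_is_connected <- function(graph) {
  if (graph$n_atoms <= 1) return(TRUE)
  seen <- logical(graph$n_atoms)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- c(graph$edges[graph$edges[, 1] %in% frontier, 2],
            graph$edges[graph$edges[, 2] %in% frontier, 1])
    frontier <- unique(nb[!seen[nb]])
    seen[frontier] <- TRUE
  }
  all(seen)
}

#' Build (and cache) molecular graphs for a whole manifest
#'
#' Graphs are computed once per distinct sequence (canonicalization runs as a
#' single batched OpenBabel call); a second call with the same cache object
#' returns stored graphs without recomputation. Records whose conversion
#' fails are collected into a `skipped` report instead of aborting the run.
#'
#' @param manifest A validated manifest tibble.
#' @param cache An environment from a previous call (or `NULL` to start one).
#' @param path Optional RDS path persisting the cache across sessions; a
#'   stored cache with a different featurizer version is discarded.
#' @return A list with `graphs` (named by record id), `skipped` (tibble of
#'   id + error message), `cache` (the environment, carrying a `computed`
#'   counter) and `version`.
#' @export
graph_cache <- function(manifest, cache = NULL, path = NULL) {
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    cache$store <- list()
    cache$computed <- 0L
    cache$version <- FEATURIZER_VERSION
    if (!is.null(path) && file.exists(path)) {
      stored <- readRDS(path)
      if (identical(stored$version, FEATURIZER_VERSION)) {
        cache$store <- stored$store
      } # else: stale featurizer version, start fresh
    }
  }
  if (!identical(cache$version, FEATURIZER_VERSION)) {
    cache$store <- list()
    cache$computed <- 0L
    cache$version <- FEATURIZER_VERSION
  }
  todo <- setdiff(unique(manifest$sequence), names(cache$store))
  if (length(todo)) {
    raw <- vapply(todo, function(s) peptide_to_smiles(s, canonical = FALSE),
                  character(1), USE.NAMES = FALSE)
    can <- canonicalize_batch(raw)
    for (j in seq_along(todo)) {
      g <- if (is.na(can[j])) {
        structure(
          class = c("aopred_smiles_error", "aopred_error", "error", "condition"),
          list(message = paste0("SMILES canonicalization failed for sequence '",
                                todo[j], "'."), call = NULL)
        )
      } else {
        tryCatch(smiles_to_graph(can[j]), aopred_error = function(e) e)
      }
      cache$computed <- cache$computed + 1L
      cache$store[[todo[j]]] <- g
    }
  }
  skipped_id <- character(0)
  skipped_msg <- character(0)
  graphs <- vector("list", nrow(manifest))
  names(graphs) <- manifest$id
  for (i in seq_len(nrow(manifest))) {
    g <- cache$store[[manifest$sequence[i]]]
    if (inherits(g, "error")) {
      skipped_id <- c(skipped_id, manifest$id[i])
      skipped_msg <- c(skipped_msg, conditionMessage(g))
      graphs[i] <- list(NULL)
    } else {
      graphs[[i]] <- g
    }
  }
  if (!is.null(path)) {
    saveRDS(list(version = FEATURIZER_VERSION, store = cache$store), path)
  }
  list(
    graphs = graphs[!vapply(graphs, is.null, logical(1))],
    skipped = tibble::tibble(id = skipped_id, message = skipped_msg),
    cache = cache,
    version = FEATURIZER_VERSION
  )
}
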