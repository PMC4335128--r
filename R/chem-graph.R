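# Molecular graphs are obtained from SMILES through ChemmineR/ChemmineOB and
# reduced to the heavy-atom skeleton: element symbols, formal charge codes and
# the bond list with (kekulized) bond orders. Parsed graphs are memoized per
# SMILES string for the lifetime of the session.

.graph_cache <- new.env(parent = emptyenv())

# Recognize a SMILES that is one lone heavy atom, optionally bracketed with
# hydrogen count and formal charge (e.g. "O", "[Na+]", "[NH4+]"). Returns a
# one-node graph, or NULL when the string is not a single atom.
single_atom_graph <- function(smiles) {
  organic <- "Br|Cl|B|C|N|O|S|P|F|I|b|c|n|o|s|p"
  if (grepl(paste0("^(", organic, ")$"), smiles)) {
    el <- toupper(substr(smiles, 1, 1))
    if (nchar(smiles) == 2) el <- paste0(el, substr(smiles, 2, 2))
    return(list(smiles = smiles, elements = el, charge = 0L,
                bonds = cbind(a1 = integer(0), a2 = integer(0),
                              order = integer(0)),
                n_atoms = 1L))
  }
  m <- regmatches(smiles, regexec(
    "^\\[([0-9]*)([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?\\]$", smiles))[[1]]
  if (length(m) == 0) return(NULL)
  el <- m[3]
  chg_s <- m[5]
  charge <- if (chg_s == "") 0L else if (chg_s %in% c("+", "-")) {
    if (chg_s == "+") 1L else -1L
  } else if (grepl("^[+-][0-9]+$", chg_s)) {
    as.integer(chg_s)
  } else {
    # runs like "++" / "--"
    sign <- if (substr(chg_s, 1, 1) == "+") 1L else -1L
    sign * nchar(chg_s)
  }
  list(smiles = smiles, elements = el, charge = charge,
       bonds = cbind(a1 = integer(0), a2 = integer(0), order = integer(0)),
       n_atoms = 1L)
}

smiles_to_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles)) {
    abort("smiles must be a single string")
  }
  hit <- get0(smiles, envir = .graph_cache, inherits = FALSE)
  if (!is.null(hit)) {
    if (identical(hit, "PARSE_FAILURE")) abort(paste0("unparseable SMILES: ", smiles))
    return(hit)
  }
  # single-atom fragments (counter-ions, water, ...) degenerate in the SDF
  # round-trip; build their one-node graph directly
  single <- single_atom_graph(smiles)
  if (!is.null(single)) {
    assign(smiles, single, envir = .graph_cache)
    return(single)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]],
    error = function(e) NULL
  )
  if (is.null(sdf)) {
    assign(smiles, "PARSE_FAILURE", envir = .graph_cache)
    abort(paste0("unparseable SMILES: ", smiles))
  }
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(elements)
  if (n == 0 || !all(grepl("^[A-Z][a-z]?$", elements))) {
    assign(smiles, "PARSE_FAILURE", envir = .graph_cache)
    abort(paste0("unparseable SMILES: ", smiles))
  }
  # MOL charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 radical, 5 -1, 6 -2, 7 -3
  charge_code <- if ("C5" %in% colnames(ab)) as.integer(ab[, "C5"]) else integer(n)
  code_map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- unname(code_map[as.character(charge_code)])
  charge[is.na(charge)] <- 0L
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- cbind(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- cbind(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  g <- list(smiles = smiles, elements = elements, charge = charge,
            bonds = bonds, n_atoms = n)
  assign(smiles, g, envir = .graph_cache)
  g
}

graph_adjacency <- function(g) {
  adj <- vector("list", g$n_atoms)
  for (i in seq_len(g$n_atoms)) adj[[i]] <- cbind(nb = integer(0), order = integer(0))
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds[k, 1]; b <- g$bonds[k, 2]; o <- g$bonds[k, 3]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  adj
}

# Per-atom canonical identifier of the circular environment of each radius.
# Radius 0 encodes element / heavy-atom degree / formal charge / bond-order
# sum; radius r nests the sorted (bond order, radius r-1 id) pairs of the
# direct neighbours inside the atom's own radius r-1 id. Two atoms share an
# id iff their neighbourhood refinements agree, which makes the ids portable
# keys for an unhashed (keyed) fingerprint. An environment at radius r > 0 is
# only emitted when its bond ball strictly grows over radius r-1, so an atom
# whose whole connected component is already covered contributes nothing new.
atom_environments <- function(g, max_radius = 2) {
  adj <- graph_adjacency(g)
  n <- g$n_atoms
  degree <- vapply(adj, nrow, integer(1))
  bondsum <- vapply(adj, function(a) sum(a[, 2]), numeric(1))
  inv <- sprintf("[%s;D%d;%+d;B%d]", g$elements, degree, g$charge, bondsum)

  # bonds within the ball of radius r around each atom
  ball_bonds <- function(dist, r) {
    if (nrow(g$bonds) == 0) return(0L)
    sum(pmin(dist[g$bonds[, 1]], dist[g$bonds[, 2]]) <= r - 1)
  }
  dists <- lapply(seq_len(n), function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        nbs <- adj[[u]][, 1]
        new <- nbs[d[nbs] == Inf]
        d[new] <- d[u] + 1
        nxt <- c(nxt, new)
      }
      frontier <- nxt
    }
    d
  })

  out <- vector("list", max_radius + 1)
  ids <- inv
  out[[1]] <- tibble(atom = seq_len(n), radius = 0L, id = paste0("r0:", ids))
  prev_bonds <- vapply(dists, ball_bonds, integer(1), r = 0L)
  for (r in seq_len(max_radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      a <- adj[[i]]
      if (nrow(a) == 0) return(paste0(ids[i], "()"))
      parts <- sort(paste0(a[, 2], "~", ids[a[, 1]]))
      paste0(ids[i], "(", paste(parts, collapse = ","), ")")
    }, character(1))
    cur_bonds <- vapply(dists, ball_bonds, integer(1), r = r)
    grew <- cur_bonds > prev_bonds
    out[[r + 1]] <- tibble(
      atom = which(grew), radius = r,
      id = paste0("r", r, ":", new_ids[grew])
    )
    ids <- new_ids
    prev_bonds <- cur_bonds
  }
  bind_rows(out)
}
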