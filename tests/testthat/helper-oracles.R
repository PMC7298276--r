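# Independent oracles for the network solver. Nothing here touches the
# package's MNA code path: equivalent resistance comes either from recursive
# series/parallel reduction of a randomly generated series-parallel topology
# tree, or from the weighted graph-Laplacian pseudoinverse.

par2 <- function(a, b) a * b / (a + b)

# Hand series/parallel reduction of the reduced splanchnic circuit,
# independent of both steady_flows() and the MNA solver.
hand_flows <- function(r_s, r_a, V = 12, r_ca = 3300, r_pda = 3300,
                       r_load = 12000) {
  r_block <- if (r_a == 0) 0 else par2(r_pda, r_a)
  r_branch <- r_ca + r_s
  r_par <- if (r_block == 0) 0 else par2(r_branch, r_block)
  i_total <- V / (r_load + r_par) * 1000
  i_ca <- if (r_block == 0) 0 else i_total * r_block / (r_branch + r_block)
  c(i_ca = i_ca, i_pda = i_total - i_ca, i_total = i_total)
}

# --- random series-parallel networks -----------------------------------------

# A series-parallel tree: leaf = resistance value; internal node = list of
# children combined in series or parallel.
random_sp_tree <- function(depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(list(kind = "leaf", r = stats::runif(1, 100, 10000)))
  kind <- sample(c("series", "parallel"), 1)
  n_children <- sample(2:3, 1)
  list(kind = kind,
       children = replicate(n_children, random_sp_tree(depth - 1),
                            simplify = FALSE))
}

# Oracle: recursive series/parallel hand reduction.
sp_reduce <- function(tree) {
  if (tree$kind == "leaf") return(tree$r)
  rs <- vapply(tree$children, sp_reduce, numeric(1))
  if (tree$kind == "series") sum(rs) else 1 / sum(1 / rs)
}

# Realise the tree as a circuit between nodes "A" and "B".
sp_to_elements <- function(tree, node_a, node_b, counter) {
  if (tree$kind == "leaf") {
    counter$n <- counter$n + 1L
    return(list(resistor(paste0("r", counter$n), node_a, node_b, tree$r)))
  }
  els <- list()
  if (tree$kind == "parallel") {
    for (ch in tree$children)
      els <- c(els, sp_to_elements(ch, node_a, node_b, counter))
  } else {
    nodes <- c(node_a, character(length(tree$children) - 1L), node_b)
    for (i in seq_len(length(tree$children) - 1L)) {
      counter$m <- counter$m + 1L
      nodes[i + 1L] <- paste0("m", counter$m)
    }
    for (i in seq_along(tree$children))
      els <- c(els, sp_to_elements(tree$children[[i]], nodes[i], nodes[i + 1L],
                                   counter))
  }
  els
}

sp_to_circuit <- function(tree) {
  counter <- new.env()
  counter$n <- 0L; counter$m <- 0L
  circuit(sp_to_elements(tree, "A", "B", counter), ground = "B")
}

# --- graph-Laplacian two-terminal resistance ---------------------------------

# R_eq(a, b) = (e_a - e_b)' L^+ (e_a - e_b), with L the conductance-weighted
# graph Laplacian over the resistive elements.
laplacian_req <- function(ckt, a, b) {
  nodes <- ckt$nodes
  L <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (el in ckt$elements) {
    if (!el$type %in% c("resistor", "potentiometer")) next
    r <- if (el$type == "resistor") el$resistance else el$value
    g <- 1 / r
    L[el$node_a, el$node_a] <- L[el$node_a, el$node_a] + g
    L[el$node_b, el$node_b] <- L[el$node_b, el$node_b] + g
    L[el$node_a, el$node_b] <- L[el$node_a, el$node_b] - g
    L[el$node_b, el$node_a] <- L[el$node_b, el$node_a] - g
  }
  Lp <- MASS::ginv(L)
  e <- stats::setNames(numeric(length(nodes)), nodes)
  e[a] <- 1; e[b] <- -1
  drop(e %*% Lp %*% e)
}

# --- KCL / Ohm audits on a solved circuit ------------------------------------

kcl_residuals <- function(sol) {
  ckt <- sol$circuit
  res <- stats::setNames(numeric(length(ckt$nodes)), ckt$nodes)
  for (el in ckt$elements) {
    i <- sol$branch_currents[[el$name]]
    res[el$node_a] <- res[el$node_a] + i  # current leaves node_a
    res[el$node_b] <- res[el$node_b] - i
  }
  res
}

ohm_residuals <- function(sol) {
  ckt <- sol$circuit
  out <- numeric(0)
  for (el in ckt$elements) {
    if (!el$type %in% c("resistor", "potentiometer")) next
    r <- if (el$type == "resistor") el$resistance else el$value
    if (r == 0) next  # shorts are checked by node-potential equality
    drop_mA <- (sol$node_potentials[[el$node_a]] -
                  sol$node_potentials[[el$node_b]]) / r * 1000
    out[el$name] <- drop_mA - sol$branch_currents[[el$name]]
  }
  out
}
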