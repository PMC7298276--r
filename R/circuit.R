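# ---- element constructors ---------------------------------------------------

#' Create a fixed resistor
#'
#' @param name Unique element name.
#' @param node_a,node_b Node labels of the two terminals (must differ).
#' @param resistance Resistance in ohms; finite and >= 0. A value of exactly
#'   0 is treated as an ideal short by the solver (an exact constraint, not a
#'   small epsilon).
#' @return An object of class `resistor`.
#' @seealso [circuit()], [solve_dc()]
#' @export
resistor <- function(name, node_a, node_b, resistance) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (identical(node_a, node_b))
    stop("resistor '", name, "': node_a and node_b must differ", call. = FALSE)
  if (!is.finite(resistance) || resistance < 0)
    stop("resistor '", name, "': resistance must be finite and >= 0", call. = FALSE)
  structure(
    list(type = "resistor", name = name,
         node_a = as.character(node_a), node_b = as.character(node_b),
         resistance = as.numeric(resistance)),
    class = c("resistor", "circuit_element"))
}

#' Create a potentiometer (variable resistor)
#'
#' A potentiometer is a resistor whose value can be swept within
#' `[r_min, r_max]`. In the splanchnic model a series potentiometer stands for
#' a vascular stenosis (resistance rises toward `r_max`) and a parallel one
#' for an aneurysm or collateral bed (resistance falls toward `r_min`).
#'
#' @param name Unique element name.
#' @param node_a,node_b Node labels of the two terminals.
#' @param value Present resistance in ohms, within `[r_min, r_max]`.
#' @param r_min,r_max Travel range in ohms, `0 <= r_min <= r_max`.
#' @return An object of class `potentiometer`.
#' @export
potentiometer <- function(name, node_a, node_b, value, r_min = 0, r_max = 50000) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (identical(node_a, node_b))
    stop("potentiometer '", name, "': node_a and node_b must differ", call. = FALSE)
  if (!is.finite(r_min) || !is.finite(r_max) || r_min < 0 || r_min > r_max)
    stop("potentiometer '", name, "': need 0 <= r_min <= r_max", call. = FALSE)
  if (!is.finite(value) || value < r_min || value > r_max)
    stop("potentiometer '", name, "': value ", value,
         " outside [", r_min, ", ", r_max, "]", call. = FALSE)
  structure(
    list(type = "potentiometer", name = name,
         node_a = as.character(node_a), node_b = as.character(node_b),
         value = as.numeric(value),
         r_min = as.numeric(r_min), r_max = as.numeric(r_max)),
    class = c("potentiometer", "circuit_element"))
}

#' Create an ideal DC voltage source
#'
#' @param name Unique element name.
#' @param node_plus,node_minus Node labels of the + and - terminals.
#' @param voltage Source voltage in volts, > 0.
#' @return An object of class `voltage_source`.
#' @export
voltage_source <- function(name, node_plus, node_minus, voltage) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (identical(node_plus, node_minus))
    stop("voltage_source '", name, "': terminals must differ", call. = FALSE)
  if (!is.finite(voltage) || voltage <= 0)
    stop("voltage_source '", name, "': voltage must be finite and > 0", call. = FALSE)
  structure(
    list(type = "voltage_source", name = name,
         node_a = as.character(node_plus), node_b = as.character(node_minus),
         voltage = as.numeric(voltage)),
    class = c("voltage_source", "circuit_element"))
}

element_resistance <- function(el) {
  switch(el$type, resistor = el$resistance, potentiometer = el$value,
         stop("element '", el$name, "' has no resistance", call. = FALSE))
}

is_resistive <- function(el) el$type %in% c("resistor", "potentiometer")

# ---- circuit ----------------------------------------------------------------

#' Assemble a DC circuit
#'
#' A circuit is a set of named nodes, a list of two-terminal elements
#' (resistors, potentiometers, at most one voltage source) and a designated
#' ground node at reference potential 0 V.
#'
#' @param elements List of elements built with [resistor()], [potentiometer()]
#'   and [voltage_source()].
#' @param ground Label of the ground node, or `NULL` to leave it undesignated
#'   (the circuit then cannot be solved until a ground is set).
#' @param nodes Optional character vector of node labels; defaults to the
#'   labels referenced by the elements. Extra declared nodes must still be
#'   reachable for the circuit to be solvable.
#' @return An object of class `circuit`.
#' @examples
#' ckt <- circuit(list(
#'   voltage_source("src", "p", "gnd", 12),
#'   resistor("load", "p", "gnd", 12000)
#' ), ground = "gnd")
#' solve_dc(ckt)
#' @export
circuit <- function(elements, ground = NULL, nodes = NULL) {
  stopifnot(is.list(elements), length(elements) > 0L)
  for (el in elements)
    if (!inherits(el, "circuit_element"))
      stop("all elements must be circuit elements", call. = FALSE)
  nms <- vapply(elements, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate element names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  used <- unique(c(vapply(elements, `[[`, character(1), "node_a"),
                   vapply(elements, `[[`, character(1), "node_b")))
  nodes <- if (is.null(nodes)) used else unique(as.character(nodes))
  if (!all(used %in% nodes))
    stop("elements reference undeclared nodes: ",
         paste(setdiff(used, nodes), collapse = ", "), call. = FALSE)
  if (!is.null(ground)) {
    ground <- as.character(ground)
    if (!ground %in% nodes)
      stop("ground node '", ground, "' is not a declared node", call. = FALSE)
  }
  names(elements) <- nms
  structure(list(nodes = nodes, elements = elements, ground = ground),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", length(x$nodes), " nodes, ", length(x$elements),
      " elements, ground = ",
      if (is.null(x$ground)) "<none>" else x$ground, "\n", sep = "")
  for (el in x$elements) {
    val <- switch(el$type,
                  resistor = paste0(el$resistance, " ohm"),
                  potentiometer = paste0(el$value, " ohm [", el$r_min, ", ", el$r_max, "]"),
                  voltage_source = paste0(el$voltage, " V"))
    cat(sprintf("  %-14s %-12s %s -- %s  %s\n", el$name, el$type,
                el$node_a, el$node_b, val))
  }
  invisible(x)
}

# breadth-first connectivity over element edges
connected_components <- function(nodes, elements) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (el in elements) {
    adj[[el$node_a]] <- c(adj[[el$node_a]], el$node_b)
    adj[[el$node_b]] <- c(adj[[el$node_b]], el$node_a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    k <- k + 1L
    queue <- start
    comp[[start]] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(comp[[w]])) { comp[[w]] <- k; queue <- c(queue, w) }
    }
  }
  comp
}

validate_solvable <- function(ckt) {
  if (is.null(ckt$ground))
    stop("circuit has no ground node designated", call. = FALSE)
  comp <- connected_components(ckt$nodes, ckt$elements)
  if (length(unique(comp)) > 1L)
    stop("circuit graph is disconnected", call. = FALSE)
  invisible(TRUE)
}

# ---- modified nodal analysis ------------------------------------------------

# Assemble and solve the extended (MNA) system. Branches with zero resistance
# and voltage sources each get a branch-current unknown and a potential
# constraint row; positive branch current flows node_a -> node_b through the
# element.
mna_solve <- function(ckt, injections = NULL) {
  free <- setdiff(ckt$nodes, ckt$ground)
  n <- length(free)
  idx <- stats::setNames(seq_len(n), free)
  aug <- Filter(function(el) el$type == "voltage_source" ||
                  (is_resistive(el) && element_resistance(el) == 0),
                ckt$elements)
  m <- length(aug)
  A <- matrix(0, n + m, n + m)
  b <- numeric(n + m)
  for (el in ckt$elements) {
    if (is_resistive(el)) {
      r <- element_resistance(el)
      if (r == 0) next  # handled as a constraint row below
      g <- 1 / r
      ia <- idx[el$node_a]; ib <- idx[el$node_b]
      if (!is.na(ia)) A[ia, ia] <- A[ia, ia] + g
      if (!is.na(ib)) A[ib, ib] <- A[ib, ib] + g
      if (!is.na(ia) && !is.na(ib)) {
        A[ia, ib] <- A[ia, ib] - g
        A[ib, ia] <- A[ib, ia] - g
      }
    }
  }
  for (j in seq_along(aug)) {
    el <- aug[[j]]
    row <- n + j
    ia <- idx[el$node_a]; ib <- idx[el$node_b]
    # KCL: current leaves node_a, enters node_b
    if (!is.na(ia)) { A[ia, row] <- A[ia, row] + 1; A[row, ia] <- A[row, ia] + 1 }
    if (!is.na(ib)) { A[ib, row] <- A[ib, row] - 1; A[row, ib] <- A[row, ib] - 1 }
    # constraint: v_a - v_b = V (0 for shorts); for a source node_a is '+'
    b[row] <- if (el$type == "voltage_source") el$voltage else 0
  }
  if (!is.null(injections))
    for (nd in names(injections)) {
      i <- idx[nd]
      if (!is.na(i)) b[i] <- b[i] + injections[[nd]]
    }
  # tol = 0: wide resistance spreads (open vs near-short edges) make the MNA
  # matrix ill-scaled but still uniquely solvable; structural singularity is
  # caught by the exact-zero-pivot error plus the residual check below.
  x <- tryCatch(solve(A, b, tol = 0), error = function(e)
    stop("singular circuit: no unique DC operating point (", conditionMessage(e), ")",
         call. = FALSE))
  resid <- max(abs(A %*% x - b))
  scale <- max(abs(A)) * max(abs(x), 1) + max(abs(b))
  if (!all(is.finite(x)) || resid > 1e-8 * scale)
    stop("singular circuit: no unique DC operating point (residual ", resid, ")",
         call. = FALSE)
  v <- stats::setNames(numeric(length(ckt$nodes)), ckt$nodes)
  v[free] <- x[seq_len(n)]
  list(potentials = v,
       aug_currents = stats::setNames(x[n + seq_len(m)],
                                      vapply(aug, `[[`, character(1), "name")))
}

#' Solve a circuit for its DC operating point
#'
#' Computes all node potentials (volts, ground = 0) and signed branch currents
#' (milliamperes) by modified nodal analysis: Kirchhoff's current law at every
#' non-ground node, with one extra branch-current unknown per voltage source
#' or zero-resistance element. Zero-resistance branches are therefore handled
#' exactly — the potentials of their endpoints are constrained equal — so a
#' fully shorted parallel branch carries all the current and its siblings
#' carry exactly none.
#'
#' @param ckt A [circuit()]. Must be connected and have a ground node.
#' @return An object of class `dc_solution`: a list with `node_potentials`
#'   (named numeric, volts) and `branch_currents` (named numeric,
#'   milliamperes; positive for conventional current flowing
#'   `node_a` -> `node_b`, i.e. from `node_plus` through a source).
#' @examples
#' ckt <- circuit(list(
#'   voltage_source("src", "p", "gnd", 12),
#'   resistor("load", "p", "gnd", 12000)
#' ), ground = "gnd")
#' sol <- solve_dc(ckt)
#' branch_current(sol, "load")  # 1 mA
#' @export
solve_dc <- function(ckt) {
  stopifnot(inherits(ckt, "circuit"))
  validate_solvable(ckt)
  res <- mna_solve(ckt)
  v <- res$potentials
  cur <- stats::setNames(numeric(length(ckt$elements)), names(ckt$elements))
  for (el in ckt$elements) {
    if (is_resistive(el) && element_resistance(el) > 0) {
      cur[el$name] <- (v[el$node_a] - v[el$node_b]) / element_resistance(el) * 1000
    } else {
      cur[el$name] <- res$aug_currents[el$name] * 1000
    }
  }
  structure(list(node_potentials = v, branch_currents = cur, circuit = ckt),
            class = "dc_solution")
}

#' @export
print.dc_solution <- function(x, ...) {
  cat("<dc_solution>\n  node potentials (V):\n")
  for (nd in names(x$node_potentials))
    cat(sprintf("    %-10s %10.6f\n", nd, x$node_potentials[[nd]]))
  cat("  branch currents (mA, node_a -> node_b):\n")
  for (nm in names(x$branch_currents))
    cat(sprintf("    %-14s %10.6f\n", nm, x$branch_currents[[nm]]))
  invisible(x)
}

#' Look up a signed branch current
#'
#' @param solution A `dc_solution` from [solve_dc()].
#' @param element_name Name of an element in the solved circuit.
#' @return Signed current in milliamperes (positive `node_a` -> `node_b`).
#' @export
branch_current <- function(solution, element_name) {
  stopifnot(inherits(solution, "dc_solution"))
  if (!element_name %in% names(solution$branch_currents))
    stop("unknown element '", element_name, "'", call. = FALSE)
  unname(solution$branch_currents[[element_name]])
}

#' Two-terminal equivalent resistance
#'
#' Measures the resistance seen between two terminals by removing
#' (open-circuiting) all voltage sources, injecting a unit test current at
#' `terminal_a`, extracting it at `terminal_b`, and reading the resulting
#' potential difference. Where the resistive network is series-parallel this
#' equals the recursive series/parallel hand reduction.
#'
#' @param ckt A [circuit()].
#' @param terminal_a,terminal_b Distinct node labels.
#' @return Equivalent resistance in ohms; `Inf` when the terminals lie in
#'   disconnected components of the source-free network.
#' @examples
#' ckt <- circuit(list(
#'   resistor("r1", "a", "b", 3300),
#'   resistor("r2", "a", "b", 3300)
#' ), ground = "b")
#' equivalent_resistance(ckt, "a", "b")  # 1650
#' @export
equivalent_resistance <- function(ckt, terminal_a, terminal_b) {
  stopifnot(inherits(ckt, "circuit"))
  terminal_a <- as.character(terminal_a); terminal_b <- as.character(terminal_b)
  if (identical(terminal_a, terminal_b))
    stop("terminals must be distinct nodes", call. = FALSE)
  if (!all(c(terminal_a, terminal_b) %in% ckt$nodes))
    stop("both terminals must be declared nodes", call. = FALSE)
  passive <- Filter(is_resistive, ckt$elements)
  if (length(passive) == 0L) return(Inf)
  comp <- connected_components(ckt$nodes, passive)
  if (comp[[terminal_a]] != comp[[terminal_b]]) return(Inf)
  sub_nodes <- names(comp)[comp == comp[[terminal_a]]]
  probe <- circuit(passive, ground = terminal_b, nodes = sub_nodes)
  inj <- stats::setNames(list(1), terminal_a)  # 1 A in at a, out at ground b
  res <- mna_solve(probe, injections = inj)
  unname(res$potentials[terminal_a])
}

# ---- fixture generator ------------------------------------------------------

#' Generate a reproducible random resistor network
#'
#' Builds a connected random network: a random spanning tree over `n_nodes`
#' nodes plus extra resistors (parallel edges allowed), with one 12 V source
#' between the ground node and a randomly chosen other node. Resistances are
#' drawn uniformly from 100 to 10000 ohms, so the network never contains
#' shorts. Intended as a solver test fixture.
#'
#' @param n_nodes Number of nodes, >= 2.
#' @param n_resistors Number of resistors, >= `n_nodes - 1`.
#' @param seed Integer seed; the generator is deterministic given the seed and
#'   leaves the caller's RNG state untouched.
#' @return A solvable [circuit()] with ground `"n1"`.
#' @export
generate_random_network <- function(n_nodes, n_resistors, seed) {
  if (n_nodes < 2) stop("need at least 2 nodes", call. = FALSE)
  if (n_resistors < n_nodes - 1)
    stop("need at least n_nodes - 1 resistors for a connected network", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    labels <- paste0("n", seq_len(n_nodes))
    els <- vector("list", n_resistors + 1L)
    # spanning tree: attach each node to a uniformly chosen earlier node
    for (i in 2:n_nodes) {
      parent <- if (i == 2) 1L else sample.int(i - 1L, 1L)
      els[[i - 1L]] <- resistor(paste0("r", i - 1L), labels[parent], labels[i],
                                stats::runif(1, 100, 10000))
    }
    for (j in seq_len(n_resistors - (n_nodes - 1L))) {
      k <- n_nodes - 1L + j
      ab <- sample.int(n_nodes, 2L)
      els[[k]] <- resistor(paste0("r", k), labels[ab[1]], labels[ab[2]],
                           stats::runif(1, 100, 10000))
    }
    els[[n_resistors + 1L]] <-
      voltage_source("src", labels[sample(2:n_nodes, 1L)], labels[1L], 12)
    circuit(els, ground = labels[1L])
  })
}

# ---- JSON serialization -----------------------------------------------------

#' Serialize a circuit to JSON
#'
#' Writes nodes, ground and all elements with their constructor fields;
#' [circuit_from_json()] round-trips the document losslessly.
#'
#' @param ckt A [circuit()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
circuit_to_json <- function(ckt, path = NULL) {
  stopifnot(inherits(ckt, "circuit"))
  doc <- list(
    nodes = ckt$nodes,
    ground = ckt$ground,
    elements = lapply(unname(ckt$elements), function(el) {
      base <- list(type = el$type, name = el$name)
      if (el$type == "voltage_source")
        c(base, list(node_plus = el$node_a, node_minus = el$node_b,
                     voltage = el$voltage))
      else if (el$type == "potentiometer")
        c(base, list(node_a = el$node_a, node_b = el$node_b,
                     r_min = el$r_min, r_max = el$r_max, value = el$value))
      else
        c(base, list(node_a = el$node_a, node_b = el$node_b,
                     resistance = el$resistance))
    }))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' Deserialize a circuit from JSON
#'
#' @param path_or_text A file path or a JSON string produced by
#'   [circuit_to_json()].
#' @return A [circuit()].
#' @export
circuit_from_json <- function(path_or_text) {
  doc <- jsonlite::fromJSON(path_or_text, simplifyVector = FALSE)
  els <- lapply(doc$elements, function(e) {
    switch(e$type,
      resistor = resistor(e$name, e$node_a, e$node_b, e$resistance),
      potentiometer = potentiometer(e$name, e$node_a, e$node_b, e$value,
                                    e$r_min, e$r_max),
      voltage_source = voltage_source(e$name, e$node_plus, e$node_minus,
                                      e$voltage),
      stop("unknown element type '", e$type, "'", call. = FALSE))
  })
  circuit(els, ground = doc$ground, nodes = unlist(doc$nodes))
}
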