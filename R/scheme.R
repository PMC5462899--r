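#' Define a Markov receptor gating scheme
#'
#' A kinetic scheme is a set of receptor states (each flagged open or shut,
#' each carrying a number of bound agonist molecules) plus directed
#' transitions between them. Transition rate constants are either
#' concentration-independent (`order = 0`, units 1/ms) or scale linearly with
#' agonist concentration (`order = 1`, units 1/mM/ms). Binding transitions
#' (`order = 1`) must increase the number of bound agonist molecules by
#' exactly one.
#'
#' @param states data.frame with columns `label` (character, unique),
#'   `open` (logical) and `n_bound` (integer count of bound agonist).
#' @param transitions data.frame with columns `from`, `to` (state labels),
#'   `rate` (non-negative rate constant) and `order` (0 or 1).
#' @param name short identifier used in printing and scheme files.
#' @return An object of class `kinetic_scheme`.
#' @seealso [scheme_biliganded()], [scheme_petrini()], [build_generator()]
#' @export
kinetic_scheme <- function(states, transitions, name = "scheme") {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  need_s <- c("label", "open", "n_bound")
  need_t <- c("from", "to", "rate", "order")
  if (!all(need_s %in% names(states)))
    stop("states must have columns: ", paste(need_s, collapse = ", "))
  if (!all(need_t %in% names(transitions)))
    stop("transitions must have columns: ", paste(need_t, collapse = ", "))
  states$label <- as.character(states$label)
  states$open <- as.logical(states$open)
  states$n_bound <- as.integer(states$n_bound)
  if (anyDuplicated(states$label))
    stop("state labels must be unique")
  if (!any(states$open))
    stop("scheme must have at least one open state")
  bad <- setdiff(c(transitions$from, transitions$to), states$label)
  if (length(bad))
    stop("transition references unknown state(s): ", paste(bad, collapse = ", "))
  if (any(transitions$rate < 0) || any(!is.finite(transitions$rate)))
    stop("rate constants must be finite and >= 0")
  if (!all(transitions$order %in% c(0L, 1L)))
    stop("concentration order must be 0 or 1")
  nb <- stats::setNames(states$n_bound, states$label)
  db <- nb[transitions$to] - nb[transitions$from]
  if (any(transitions$order == 1 & db != 1L))
    stop("binding transitions (order 1) must increase n_bound by exactly 1")
  structure(list(states = states, transitions = transitions, name = name),
            class = "kinetic_scheme")
}

#' @exportS3Method base::print
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", nrow(x$states), " states (",
      sum(x$states$open), " open), ", nrow(x$transitions),
      " transitions\n", sep = "")
  op <- ifelse(x$states$open, "*", "")
  cat("  states:", paste0(x$states$label, op, "(", x$states$n_bound, ")",
                          collapse = " "), "\n")
  tr <- x$transitions
  u <- ifelse(tr$order == 1, "/mM/ms", "/ms")
  cat(sprintf("  %s -> %s  %g %s\n", format(tr$from), format(tr$to),
              tr$rate, u), sep = "")
  invisible(x)
}

n_states <- function(scheme) nrow(scheme$states)

state_index <- function(scheme, labels) {
  match(labels, scheme$states$label)
}

#' Linear bi-liganded gating scheme template
#'
#' A classic sequential scheme for a receptor with two agonist binding sites:
#' `C <-> CA <-> CA2 <-> O`, with an optional desensitized state `D`
#' reachable from the fully bound shut state. Openings occur only from the
#' doubly bound state. Default rate constants are placeholders chosen so
#' that the deactivation of the open-state occupancy after a brief
#' millisecond-scale agonist pulse has a mono-exponential time constant in
#' the 10-20 ms range typical of fast GABAergic currents. Agonist
#' unbinding is slow relative to that decay (the transmitter is held
#' through gating and desensitization cycles), so the synaptic decay is a
#' per-receptor property rather than a function of rebinding in the
#' cluster. Every rate is configurable.
#'
#' @param kon1,kon2 binding rate constants (1/mM/ms) for the first and
#'   second agonist molecule.
#' @param koff1,koff2 unbinding rate constants (1/ms).
#' @param beta,alpha opening and closing rate constants (1/ms).
#' @param d_rate,r_rate desensitization and recovery rate constants (1/ms).
#' @param desensitized include the desensitized state?
#' @return A `kinetic_scheme`.
#' @export
scheme_biliganded <- function(kon1 = 20, kon2 = 10, koff1 = 0.8,
                              koff2 = 0.06, beta = 2, alpha = 1,
                              d_rate = 0.3, r_rate = 0.09,
                              desensitized = TRUE) {
  st <- data.frame(label = c("C", "CA", "CA2", "O"),
                   open = c(FALSE, FALSE, FALSE, TRUE),
                   n_bound = c(0L, 1L, 2L, 2L))
  tr <- data.frame(
    from = c("C", "CA", "CA", "CA2", "CA2", "O"),
    to   = c("CA", "C", "CA2", "CA", "O", "CA2"),
    rate = c(kon1, koff1, kon2, koff2, beta, alpha),
    order = c(1L, 0L, 1L, 0L, 0L, 0L))
  if (desensitized) {
    st <- rbind(st, data.frame(label = "D", open = FALSE, n_bound = 2L))
    tr <- rbind(tr, data.frame(from = c("CA2", "D"), to = c("D", "CA2"),
                               rate = c(d_rate, r_rate), order = c(0L, 0L)))
  }
  kinetic_scheme(st, tr, name = "biliganded")
}

#' Gating scheme template with mono-liganded openings and cooperative binding
#'
#' A structurally different template in which the singly bound receptor can
#' already open (to a low-efficacy open state), binding of the second
#' agonist molecule is cooperative (faster than the first), and the fully
#' bound shut state can desensitize. Default rates are placeholders tuned
#' the same way as [scheme_biliganded()] (brief-pulse deactivation in the
#' 10-20 ms range) and are all configurable.
#'
#' @param kon1,kon2 binding rate constants (1/mM/ms); `kon2 > kon1` gives
#'   cooperative binding.
#' @param koff1,koff2 unbinding rate constants (1/ms).
#' @param beta1,alpha1 opening/closing rates of the mono-liganded open state.
#' @param beta2,alpha2 opening/closing rates of the bi-liganded open state.
#' @param d_rate,r_rate desensitization and recovery rates (1/ms).
#' @return A `kinetic_scheme`.
#' @export
scheme_petrini <- function(kon1 = 10, kon2 = 30, koff1 = 0.8,
                           koff2 = 0.06, beta1 = 0.1, alpha1 = 6,
                           beta2 = 2, alpha2 = 1,
                           d_rate = 0.3, r_rate = 0.09) {
  st <- data.frame(
    label = c("C", "CA", "CA2", "O1", "O2", "D"),
    open = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    n_bound = c(0L, 1L, 2L, 1L, 2L, 2L))
  tr <- data.frame(
    from = c("C", "CA", "CA", "CA2", "CA", "O1", "CA2", "O2", "CA2", "D"),
    to   = c("CA", "C", "CA2", "CA", "O1", "CA", "O2", "CA2", "D", "CA2"),
    rate = c(kon1, koff1, kon2, koff2, beta1, alpha1, beta2, alpha2,
             d_rate, r_rate),
    order = c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  kinetic_scheme(st, tr, name = "petrini")
}

#' Build the infinitesimal generator matrix of a scheme
#'
#' Returns the square rate matrix Q (1/ms) at a given agonist concentration:
#' `Q[i, j]` for `i != j` is the transition rate from state i to state j
#' (order-1 rates multiplied by the concentration), and each diagonal entry
#' is minus its row sum, so rows sum to zero.
#'
#' @param scheme a [kinetic_scheme()].
#' @param concentration agonist concentration in mM (>= 0).
#' @return Square numeric matrix with state labels as dimnames.
#' @export
build_generator <- function(scheme, concentration) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(concentration) || concentration < 0)
    stop("concentration must be a finite non-negative value (mM)")
  n <- n_states(scheme)
  Q <- matrix(0, n, n, dimnames = list(scheme$states$label,
                                       scheme$states$label))
  tr <- scheme$transitions
  i <- state_index(scheme, tr$from)
  j <- state_index(scheme, tr$to)
  k <- tr$rate * ifelse(tr$order == 1, concentration, 1)
  for (r in seq_along(i)) Q[i[r], j[r]] <- Q[i[r], j[r]] + k[r]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Check microscopic reversibility (detailed balance) on cycles
#'
#' For every independent cycle of the scheme's transition graph, compares the
#' product of rate constants going one way around with the product going the
#' other way (Kolmogorov's criterion, with order-1 rates evaluated at the
#' given concentration). Cycles whose forward/backward products differ, or
#' that contain an edge with no reverse transition, violate microscopic
#' reversibility. This is a report-only diagnostic: irreversible schemes are
#' legitimate models.
#'
#' @param scheme a [kinetic_scheme()].
#' @param concentration agonist concentration (mM) at which order-1 rates
#'   are evaluated.
#' @param tol relative tolerance for product comparison.
#' @return data.frame with one row per independent cycle: the cycle (as a
#'   label path), forward and backward rate products, and a `reversible`
#'   flag. Zero rows if the graph is a tree (no cycles).
#' @export
detailed_balance_check <- function(scheme, concentration = 1, tol = 1e-8) {
  Q <- build_generator(scheme, concentration)
  diag(Q) <- 0
  n <- nrow(Q)
  adj <- (Q > 0) | (t(Q) > 0)   # undirected support
  # spanning forest by BFS; non-tree edges close independent cycles
  parent <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  tree_edge <- matrix(FALSE, n, n)
  for (root in seq_len(n)) {
    if (seen[root]) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] & !seen)) {
        seen[w] <- TRUE; parent[w] <- v
        tree_edge[v, w] <- tree_edge[w, v] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  path_to_root <- function(v) {
    p <- v
    while (!is.na(parent[v])) { v <- parent[v]; p <- c(p, v) }
    p
  }
  res <- list()
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a || !adj[a, b] || tree_edge[a, b]) next
    pa <- path_to_root(a); pb <- path_to_root(b)
    common <- intersect(pa, pb)
    meet <- common[which.min(match(common, pa))]
    cyc <- c(rev(pa[seq_len(match(meet, pa))]), b)
    if (match(meet, pb) > 1)
      cyc <- c(cyc, rev(pb[seq_len(match(meet, pb) - 1)])[-1], cyc[1])
    else cyc <- c(cyc, cyc[1])
    fwd <- prod(Q[cbind(cyc[-length(cyc)], cyc[-1])])
    bwd <- prod(Q[cbind(cyc[-1], cyc[-length(cyc)])])
    ok <- (fwd > 0 && bwd > 0 &&
             abs(fwd - bwd) <= tol * max(fwd, bwd)) ||
      (fwd == 0 && bwd == 0)
    res[[length(res) + 1]] <- data.frame(
      cycle = paste(scheme$states$label[cyc], collapse = "-"),
      forward_product = fwd, backward_product = bwd, reversible = ok)
  }
  if (!length(res))
    return(data.frame(cycle = character(), forward_product = numeric(),
                      backward_product = numeric(), reversible = logical()))
  do.call(rbind, res)
}

#' Write a scheme definition file
#'
#' Plain-text key-value format, one record per line:
#' `name: <id>`, `state: <label> open=<0|1> bound=<n>` and
#' `transition: <from> <to> rate=<k> order=<0|1>`. Round-trips losslessly
#' through [read_scheme()].
#'
#' @param scheme a [kinetic_scheme()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  st <- scheme$states
  tr <- scheme$transitions
  lines <- c(
    paste0("name: ", scheme$name),
    sprintf("state: %s open=%d bound=%d", st$label, as.integer(st$open),
            st$n_bound),
    sprintf("transition: %s %s rate=%.17g order=%d", tr$from, tr$to,
            tr$rate, tr$order))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scheme definition file
#'
#' @param path file written by [write_scheme()] (or hand-authored in the
#'   same format; blank lines and `#` comments are ignored).
#' @return A [kinetic_scheme()].
#' @export
read_scheme <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- function(tok, key) {
    hit <- grep(paste0("^", key, "="), tok, value = TRUE)
    if (!length(hit)) stop("scheme file: missing ", key, " in: ",
                           paste(tok, collapse = " "))
    sub(paste0("^", key, "="), "", hit[1])
  }
  name <- "scheme"
  st <- list(); tr <- list()
  for (ln in lines) {
    if (startsWith(ln, "name:")) {
      name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "state:")) {
      tok <- strsplit(trimws(sub("^state:", "", ln)), "[[:space:]]+")[[1]]
      st[[length(st) + 1]] <- data.frame(
        label = tok[1], open = as.integer(kv(tok, "open")) > 0,
        n_bound = as.integer(kv(tok, "bound")))
    } else if (startsWith(ln, "transition:")) {
      tok <- strsplit(trimws(sub("^transition:", "", ln)),
                      "[[:space:]]+")[[1]]
      tr[[length(tr) + 1]] <- data.frame(
        from = tok[1], to = tok[2], rate = as.numeric(kv(tok, "rate")),
        order = as.integer(kv(tok, "order")))
    } else stop("scheme file: unrecognized line: ", ln)
  }
  if (!length(st)) stop("scheme file contains no states")
  kinetic_scheme(do.call(rbind, st), do.call(rbind, tr), name = name)
}
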