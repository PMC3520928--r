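# Cumulative net fluxes between connected macrobasins and DOT export.

#' Cumulative net flux matrix
#'
#' Integrates the instantaneous net flux on every Hamming-1 edge,
#' \deqn{J_{ab}(\tau) = \int_0^\tau \left[K_{a \leftarrow b} P_b(t) -
#'   K_{b \leftarrow a} P_a(t)\right] dt,}
#' analytically per spectral mode: a decaying mode contributes
#' (e^(lambda tau) - 1)/lambda, and the stationary (lambda = 0) component
#' contributes nothing because detailed balance makes its per-edge net flux
#' vanish. `tau = Inf` uses -1/lambda and is exact in the equilibrium limit.
#'
#' @param decomp A `spectral_decomposition` of `K`.
#' @param K The `rate_matrix` the decomposition came from.
#' @param P0 Initial population vector (named or in label order), e.g. all
#'   mass on the fully unfolded or fully folded macrobasin.
#' @param tau Time horizon (finite, or `Inf` for the equilibrium limit).
#' @return A `flux_matrix`: antisymmetric matrix with entry (a, b) = net
#'   flux from b into a over [0, tau], attributes `tau`, `P0`, `pi`.
#' @export
cumulative_flux <- function(decomp, K, P0, tau = Inf) {
  labels <- decomp$labels
  stopifnot(identical(rownames(K), labels))
  P0 <- normalize_populations(P0, labels)
  lam <- Re(decomp$values)
  tol <- 1e-10 * decomp$k0
  decaying <- lam <= -tol
  if (is.infinite(tau) && any(lam > tol)) {
    stop("tau = Inf undefined for a non-relaxing spectrum", call. = FALSE)
  }
  co <- as.numeric(decomp$vectors_inv %*% P0)
  tint <- numeric(length(lam))  # integral of e^(lambda t) over [0, tau]
  tint[decaying] <- if (is.infinite(tau)) {
    -1 / lam[decaying]
  } else {
    (exp(lam[decaying] * tau) - 1) / lam[decaying]
  }
  # time-integrated deviation of each state's population from the
  # stationary component; zero mode dropped (no net flux under detailed
  # balance)
  Iint <- as.numeric(Re(decomp$vectors %*% (co * tint)))
  Km <- unclass(K)
  diag(Km) <- 0
  Jin <- Km * rep(Iint, each = nrow(Km))  # K[a<-b] * Iint_b
  J <- Jin - t(Jin)
  dimnames(J) <- dimnames(K)
  attr(J, "tau") <- tau
  attr(J, "P0") <- stats::setNames(P0, labels)
  attr(J, "pi") <- stats::setNames(decomp$pi, labels)
  class(J) <- c("flux_matrix", "matrix")
  J
}

#' Conservation residual across a cut
#'
#' For any subset S of macrobasins, the total net flux into S over
#' [0, Inf) must equal the equilibrium population of S minus its initial
#' population. Returns the absolute residual of that identity.
#'
#' @param J A `flux_matrix` at `tau = Inf`.
#' @param subset Character vector of labels forming the cut set (nonempty,
#'   proper).
#' @param P0,Peq Initial and equilibrium population vectors (default: taken
#'   from `J`'s attributes).
#' @return Nonnegative residual.
#' @export
cut_balance <- function(J, subset, P0 = attr(J, "P0"),
                        Peq = attr(J, "pi")) {
  labels <- rownames(J)
  stopifnot(all(subset %in% labels), length(subset) >= 1L)
  inS <- labels %in% subset
  if (all(inS)) return(abs(sum(Peq) - sum(P0)))  # whole set: 0 by normalization
  flux_in <- sum(J[inS, !inS, drop = FALSE])
  abs(flux_in - (sum(Peq[inS]) - sum(P0[inS])))
}

#' Export a flux diagram as GraphViz DOT text
#'
#' One node per sampled macrobasin, annotated with its label and free energy
#' in k_B*T in parentheses. Position hints place y proportional to -F
#' (stable basins low) and x proportional to the fraction of folded bits (a
#' proxy for the global reaction coordinate). Edges are directed along the
#' net flux sign with pen widths proportional to |J| normalized to the
#' maximum flux, floored at `min_width` so that small fluxes stay visible.
#' Output is deterministic: nodes and edges in sorted label order.
#'
#' @param J A `flux_matrix`.
#' @param table The matching `free_energy_table`.
#' @param min_width Minimum pen width in render units (default 0.1).
#' @param direction Graph name annotation, `"folding"` or `"unfolding"`.
#' @param max_width Pen width given to the largest |flux| (default 5).
#' @return A single string of DOT text.
#' @export
export_flux_dot <- function(J, table, min_width = 0.1,
                            direction = c("folding", "unfolding"),
                            max_width = 5) {
  direction <- match.arg(direction)
  labels <- sort(rownames(J))
  if (length(labels) == 0L) stop("empty flux matrix", call. = FALSE)
  if (!setequal(labels, table$label)) {
    stop("flux matrix and free-energy table label sets differ",
         call. = FALSE)
  }
  F <- stats::setNames(table$F_kT, table$label)[labels]
  xfrac <- label_nfolded(labels) / nchar(labels[1L])
  jmax <- max(abs(unclass(J)))
  lines <- c(sprintf("digraph %s {", direction),
             "  graph [splines=line];",
             "  node [shape=box];")
  for (i in seq_along(labels)) {
    l <- labels[i]
    lines <- c(lines, sprintf(
      '  "%s" [label="%s\\n(%.2f)", pos="%.3f,%.3f!"];',
      l, l, F[[l]], 4 * xfrac[i], -F[[l]]))
  }
  for (a in labels) for (b in labels) {
    if (a < b && (J[b, a] != 0 || hamming(a, b) == 1L)) {
      jab <- J[b, a]  # net flux a -> b
      src <- if (jab >= 0) a else b
      dst <- if (jab >= 0) b else a
      w <- if (jmax > 0) max(min_width, max_width * abs(jab) / jmax)
           else min_width
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [penwidth=%.4f, label="%.3g"];',
        src, dst, w, abs(jab)))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Dominant pathway by widest bottleneck
#'
#' On the directed graph whose edge a -> b carries the positive net flux
#' J_ba, finds the source-to-sink path maximizing the minimum edge flux
#' (the widest-bottleneck path), breaking ties lexicographically by label
#' sequence. This is the single pathway a flux diagram's thickest chain of
#' arrows traces out.
#'
#' @param J A `flux_matrix`.
#' @param source,sink Macrobasin labels.
#' @return Character vector of labels from source to sink, with the
#'   bottleneck flux as attribute `bottleneck`.
#' @export
dominant_pathway <- function(J, source, sink) {
  labels <- rownames(J)
  stopifnot(source %in% labels, sink %in% labels)
  # Phase 1 - widest-path Dijkstra for the optimal bottleneck width W.
  best <- stats::setNames(rep(-Inf, length(labels)), labels)
  best[source] <- Inf
  done <- stats::setNames(rep(FALSE, length(labels)), labels)
  repeat {
    open <- which(!done & best > -Inf)
    if (length(open) == 0L) break
    u <- names(open)[which.max(best[open])]
    done[u] <- TRUE
    if (u == sink) break
    for (v in labels[J[, u] > 0 & !done]) {  # J[b, u] > 0: net flux u -> b
      best[v] <- max(best[v], min(best[u], J[v, u]))
    }
  }
  W <- best[sink]
  if (!is.finite(W) || W <= 0) {
    stop("no positive-flux path from ", source, " to ", sink, call. = FALSE)
  }
  # Phase 2 - restrict to edges carrying at least W and take the first
  # sink-reaching simple path of a DFS that explores neighbours in label
  # order: that enumeration order is lexicographic on vertex sequences,
  # so the first hit is the lexicographically smallest optimal path.
  dfs <- function(node, visited) {
    if (node == sink) return(visited)
    for (v in sort(labels[J[, node] >= W - 1e-15 * W & J[, node] > 0])) {
      if (!(v %in% visited)) {
        got <- dfs(v, c(visited, v))
        if (!is.null(got)) return(got)
      }
    }
    NULL
  }
  path <- dfs(source, source)
  if (is.null(path)) {
    stop("no positive-flux path from ", source, " to ", sink, call. = FALSE)
  }
  structure(path, bottleneck = unname(W))
}

#' Write a flux matrix as an edge-list TSV
#'
#' Columns: `from_label`, `to_label`, `net_flux` (positive direction only,
#' sorted).
#' @param J A `flux_matrix`.
#' @param path File path.
#' @export
write_flux_table <- function(J, path) {
  labels <- rownames(J)
  rows <- list()
  for (a in labels) for (b in labels) {
    if (a < b && J[b, a] != 0) {
      jab <- J[b, a]
      rows[[length(rows) + 1L]] <- data.frame(
        from_label = if (jab > 0) a else b,
        to_label = if (jab > 0) b else a,
        net_flux = abs(jab))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from_label = character(0), to_label = character(0),
               net_flux = numeric(0))
  df <- df[order(df$from_label, df$to_label), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
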