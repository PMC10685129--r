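#' Recursive subset scan for higher-order dependencies
#'
#' Runs the joint-independence test on every subset of variables of size
#' `2 .. d_max` and flags *emergent* dependencies: subsets whose joint
#' independence is rejected while no proper subset (of size >= 2) is
#' rejected. Since joint independence of a set implies joint independence of
#' all its subsets, an emergent ("first-time") rejection marks dependence
#' that cannot be explained by lower-order structure.
#'
#' Gram matrices and bandwidths are computed once per variable and reused
#' across subsets. Each subset's resampling plan is seeded deterministically
#' from `(seed, sorted subset labels)`, so results do not depend on the
#' order in which subsets are visited. For the shifting scheme the minimum
#' lag `h` is recomputed from the pooled series of each subset's variables.
#'
#' No multiplicity correction is applied by default (per-subset decisions at
#' raw `alpha`); `multiplicity = "holm"` or `"bh"` adjusts p-values within
#' each subset order before deciding.
#'
#' @inheritParams dhsic_test
#' @param d_max largest subset size to test, between 2 and `d`.
#' @param multiplicity `"none"` (default), `"holm"` or `"bh"`; applied per
#'   subset order.
#' @return An object of class `"dhsic_scan"`: list with `results` (named
#'   list of [dhsic_test()] objects, names are comma-joined variable
#'   subsets), `table` (one row per subset: variables, order, statistic,
#'   p-value, rejected, emergent), `alpha`, `d_max`, `scheme`, `seed`.
#' @examples
#' d <- sim_ar_pairwise_coupled(T = 120, lambda = 1.5, seed = 3)
#' sc <- dhsic_scan(d, resamples = 60, seed = 3)
#' sc
#' @export
dhsic_scan <- function(data, scheme = c("auto", "shift", "permute"),
                       spec = kernel_spec(), resamples = 200L, alpha = 0.05,
                       d_max = NULL, seed = 1L,
                       multiplicity = c("none", "holm", "bh")) {
  scheme <- match.arg(scheme)
  multiplicity <- match.arg(multiplicity)
  if (scheme == "auto")
    scheme <- if (inherits(data, "multireal_dataset")) "permute" else "shift"
  d <- data$d
  if (is.null(d_max)) d_max <- d
  if (d_max < 2L || d_max > d) stop("`d_max` must be between 2 and d")
  vars <- data$variable_names

  results <- list()
  for (size in 2:d_max) {
    for (members in combn(vars, size, simplify = FALSE)) {
      sub <- subset_dataset(data, members)
      sub_seed <- derive_seed(seed, paste(sort(members), collapse = ","))
      key <- paste(members, collapse = ",")
      results[[key]] <- dhsic_test(sub, scheme = scheme, spec = spec,
                                   resamples = resamples, alpha = alpha,
                                   seed = sub_seed)
    }
  }

  pvals <- vapply(results, function(r) r$p_value, numeric(1))
  orders <- vapply(results, function(r) r$d, integer(1))
  adj <- pvals
  if (multiplicity != "none") {
    method <- if (multiplicity == "holm") "holm" else "BH"
    for (size in unique(orders)) {
      sel <- orders == size
      adj[sel] <- stats::p.adjust(pvals[sel], method = method)
    }
  }
  rejected <- alpha > adj
  for (k in seq_along(results)) {
    results[[k]]$p_adjusted <- adj[[k]]
    results[[k]]$rejected <- rejected[[k]]
  }

  emergent <- emergent_flags(names(results), rejected)
  table <- data.frame(
    variables = names(results),
    order = orders,
    statistic = vapply(results, function(r) r$statistic, numeric(1)),
    p_value = pvals,
    p_adjusted = adj,
    rejected = rejected,
    emergent = emergent,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(results = results, table = table, alpha = alpha,
                 d_max = d_max, scheme = scheme, seed = seed,
                 multiplicity = multiplicity,
                 variable_names = vars),
            class = "dhsic_scan")
}

# Bottom-up emergent flags from subset keys ("a,b,c") and rejection status.
emergent_flags <- function(keys, rejected) {
  members <- strsplit(keys, ",", fixed = TRUE)
  names(rejected) <- keys
  vapply(seq_along(keys), function(i) {
    if (!rejected[[i]]) return(FALSE)
    mem <- members[[i]]
    for (j in seq_along(keys)) {
      other <- members[[j]]
      if (length(other) < length(mem) && all(other %in% mem) && rejected[[j]])
        return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' @export
print.dhsic_scan <- function(x, ...) {
  cat("\n\tRecursive dHSIC subset scan\n\n")
  cat(sprintf("%d variables, subsets of size 2..%d, scheme = %s, alpha = %g%s\n",
              length(x$variable_names), x$d_max, x$scheme, x$alpha,
              if (x$multiplicity == "none") "" else
                sprintf(" (%s-adjusted per order)", x$multiplicity)))
  nrej <- sum(x$table$rejected)
  neme <- sum(x$table$emergent)
  cat(sprintf("%d of %d subsets rejected; %d emergent\n\n",
              nrej, nrow(x$table), neme))
  tab <- x$table
  tab$statistic <- signif(tab$statistic, 4)
  tab$p_value <- signif(tab$p_value, 4)
  if (x$multiplicity == "none") tab$p_adjusted <- NULL
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dhsic_scan <- function(object, ...) {
  print(object)
  em <- object$table$variables[object$table$emergent]
  if (length(em))
    cat("\nemergent dependencies:", paste(em, collapse = "; "), "\n")
  invisible(object)
}

#' Dependency hypergraph from a subset scan
#'
#' Maps the rejected (or only the emergent) subsets of a [dhsic_scan()] onto
#' a hypergraph: nodes are variables, each hyperedge records the member set,
#' its order, its p-value and whether it is emergent.
#'
#' @param scan a `"dhsic_scan"` object.
#' @param mode `"all_rejections"` (one hyperedge per rejected subset) or
#'   `"emergent_only"`.
#' @return An object of class `"dhsic_hypergraph"`: list with `nodes` and
#'   `hyperedges` (list of lists with `members`, `order`, `p_value`,
#'   `emergent`).
#' @examples
#' d <- sim_ar_pairwise_coupled(T = 120, lambda = 1.5, seed = 3)
#' hg <- as_hypergraph(dhsic_scan(d, resamples = 60, seed = 3))
#' hg
#' @export
as_hypergraph <- function(scan, mode = c("all_rejections", "emergent_only")) {
  stopifnot(inherits(scan, "dhsic_scan"))
  mode <- match.arg(mode)
  tab <- scan$table
  keep <- if (mode == "emergent_only") tab$emergent else tab$rejected
  edges <- lapply(which(keep), function(i) {
    list(members = strsplit(tab$variables[i], ",", fixed = TRUE)[[1L]],
         order = tab$order[i],
         p_value = tab$p_value[i],
         emergent = tab$emergent[i])
  })
  structure(list(nodes = scan$variable_names, hyperedges = edges, mode = mode),
            class = "dhsic_hypergraph")
}

#' @export
print.dhsic_hypergraph <- function(x, ...) {
  cat(sprintf("Dependency hypergraph (%s): %d nodes, %d hyperedges\n",
              x$mode, length(x$nodes), length(x$hyperedges)))
  for (e in x$hyperedges)
    cat(sprintf("  {%s}  order %d, p = %.4g%s\n",
                paste(e$members, collapse = ", "), e$order, e$p_value,
                if (e$emergent) ", emergent" else ""))
  invisible(x)
}

#' Plot a dependency hypergraph
#'
#' Draws nodes on a circle; pairwise edges as lines, higher-order hyperedges
#' as shaded convex polygons over their members. Uses base graphics.
#'
#' @param x a `"dhsic_hypergraph"`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.dhsic_hypergraph <- function(x, ...) {
  n <- length(x$nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  xy <- cbind(cos(theta), sin(theta))
  rownames(xy) <- x$nodes
  graphics::plot(xy, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", pch = 19, ...)
  for (e in x$hyperedges) {
    pts <- xy[e$members, , drop = FALSE]
    if (nrow(pts) == 2L) {
      graphics::lines(pts, lwd = 2,
                      col = if (e$emergent) "firebrick" else "grey30")
    } else {
      graphics::polygon(pts[grDevices::chull(pts), , drop = FALSE],
                        border = NA,
                        col = grDevices::adjustcolor(
                          if (e$emergent) "firebrick" else "steelblue", 0.3))
    }
  }
  graphics::points(xy, pch = 19)
  graphics::text(xy * 1.17, labels = x$nodes)
  invisible(x)
}

#' Write a scan report as JSON
#'
#' One record per tested subset with full provenance (variables, statistic,
#' raw and adjusted p-values, decision, emergent flag, scheme, resample
#' count, seed and per-variable bandwidths), sufficient to re-run the
#' identical test.
#'
#' @param scan a `"dhsic_scan"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_json <- function(scan, path) {
  stopifnot(inherits(scan, "dhsic_scan"))
  em <- scan$table$emergent
  records <- lapply(seq_along(scan$results), function(i) {
    r <- scan$results[[i]]
    list(variables = r$variables, statistic = r$statistic,
         p_value = r$p_value, p_adjusted = r$p_adjusted,
         alpha = r$alpha, rejected = r$rejected, emergent = em[[i]],
         scheme = r$scheme, resamples = r$resamples, seed = r$seed,
         sigmas_used = as.list(stats::setNames(r$sigmas, r$variables)),
         h = r$h)
  })
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a hyperedge list as plain text
#'
#' One line per hyperedge, members comma-separated, for consumption by
#' external graph tools.
#'
#' @param hypergraph a `"dhsic_hypergraph"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hyperedges <- function(hypergraph, path) {
  stopifnot(inherits(hypergraph, "dhsic_hypergraph"))
  lines <- vapply(hypergraph$hyperedges,
                  function(e) paste(e$members, collapse = ","), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a hypergraph as JSON
#'
#' @inheritParams write_hyperedges
#' @return `path`, invisibly.
#' @export
write_hypergraph_json <- function(hypergraph, path) {
  stopifnot(inherits(hypergraph, "dhsic_hypergraph"))
  jsonlite::write_json(
    list(nodes = hypergraph$nodes, mode = hypergraph$mode,
         hyperedges = hypergraph$hyperedges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
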