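#' Sample a graph from an edge-probability model
#'
#' Each unordered pair `i < j` is included independently with probability
#' `p(i, j)` (a Bernoulli trial per pair). The output is fully determined by
#' `(model, seed)`: the uniform draws are consumed row by row in a fixed
#' order, independent of the internal block size.
#'
#' @param model An `edge_model`.
#' @param seed Integer RNG seed.
#' @param block Row-block size for probability evaluation.
#' @return An `undirected_graph` on the model's `n` vertices.
#' @export
sample_graph <- function(model, seed, block = 256L) {
  n <- model$emb$n
  out <- vector("list", max(n - 1L, 0L))
  with_seed(seed, {
    if (n >= 2L) {
      for (start in seq(1L, n - 1L, by = block)) {
        rows <- start:min(start + block - 1L, n - 1L)
        p <- prob_rows(model, rows)
        for (k in seq_along(rows)) {
          i <- rows[k]
          js <- (i + 1L):n
          hit <- js[stats::runif(length(js)) < p[k, js]]
          if (length(hit) > 0L) out[[i]] <- cbind(i, hit)
        }
      }
    }
  })
  edges <- do.call(rbind, out)
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  undirected_graph(edges, n = n)
}

#' Replicate audit: max-density degree-triangle curve over samples
#'
#' Draws `replicates` independent graphs from the model (replicate `r` uses
#' the counter-derived seed `(seed + r * 1000003) mod (2^31 - 1)`), computes
#' each sample's degree-triangle curve, and reports the pointwise maximum
#' density over replicates on the union of all thresholds, with each curve
#' extended as a step function (0 below its smallest threshold, its
#' total-triangle density above its largest).
#'
#' @param model An `edge_model`.
#' @param replicates Number of samples, at least 1.
#' @param seed Base integer seed.
#' @return A `sample_summary`: list with `replicates`, `seed`, `seeds`,
#'   `curves` (per-replicate `degree_triangle_curve`s), `max_curve`
#'   (a `degree_triangle_curve` on the merged grid), and `edge_counts`
#'   with mean/min/max sampled edges.
#' @export
replicate_audit <- function(model, replicates, seed) {
  if (replicates < 1L) stop("`replicates` must be at least 1")
  seeds <- (seed + seq_len(replicates) * 1000003) %% 2147483647
  curves <- vector("list", replicates)
  sizes <- integer(replicates)
  for (r in seq_len(replicates)) {
    g <- sample_graph(model, seeds[r])
    sizes[r] <- graph_size(g)
    curves[[r]] <- degree_triangle_curve(g)
  }
  grid <- sort(unique(unlist(lapply(curves, `[[`, "thresholds"))))
  t_max <- rep(0L, length(grid))
  for (cv in curves) t_max <- pmax(t_max, curve_at(cv, grid)$T)
  n <- model$emb$n
  structure(list(replicates = replicates, seed = seed, seeds = seeds,
                 curves = curves,
                 max_curve = structure(list(thresholds = grid,
                                            triangles = as.integer(t_max),
                                            delta = if (n > 0L) t_max / n
                                                    else numeric(0),
                                            n = n),
                                       class = "degree_triangle_curve"),
                 edge_sizes = sizes,
                 edge_counts = list(mean = mean(sizes), min = min(sizes),
                                    max = max(sizes))),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf(
    "sample_summary: %d replicates, edges %g (min %d, max %d)\n",
    x$replicates, x$edge_counts$mean, x$edge_counts$min, x$edge_counts$max))
  invisible(x)
}

#' Export a sample summary
#'
#' Writes the max-density curve as TSV (columns `c`, `T_max`, `delta_max`)
#' and the run metadata (model hash, seeds, per-replicate edge counts) as
#' JSON.
#'
#' @param summary A `sample_summary`.
#' @param model The `edge_model` the summary was drawn from (hashed into the
#'   metadata).
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the metadata list.
#' @export
write_sample_summary <- function(summary, model, tsv_path = NULL,
                                 json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(c = summary$max_curve$thresholds,
                     T_max = summary$max_curve$triangles,
                     delta_max = summary$max_curve$delta)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(model_to_json(model), tmp)
  meta <- list(model_hash = unname(tools::md5sum(tmp)),
               variant = model$variant,
               base_seed = summary$seed,
               replicate_seeds = summary$seeds,
               replicate_edges = summary$edge_sizes,
               edge_counts = summary$edge_counts)
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               json_path)
  }
  invisible(meta)
}
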