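#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a TEBC field
#'
#' @param x a `tebc_field` from [tebc_scores()].
#' @param ... unused.
#' @return A tibble `edge_id`, `score`.
#' @method tidy tebc_field
#' @export
tidy.tebc_field <- function(x, ...) {
  tibble::tibble(edge_id = x$edge_id, score = x$score)
}

#' @rdname tidy.tebc_field
#' @method glance tebc_field
#' @export
glance.tebc_field <- function(x, ...) {
  disp <- tebc_dispersion(x)
  org <- attr(x, "origins")
  tibble::tibble(n_edges = nrow(x), max_score = disp$max_score,
                 gini = disp$gini, n_positive = disp$n_positive,
                 total_score = sum(x$score),
                 n_origins = nrow(org), n_skipped = attr(x, "n_skipped"))
}

#' Tidy an edge criticality delta
#'
#' @param x an `edge_criticality` from [tebc_delta()].
#' @param ... unused.
#' @return The per-edge tibble (already tidy).
#' @method tidy edge_criticality
#' @export
tidy.edge_criticality <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.edge_criticality
#' @method glance edge_criticality
#' @export
glance.edge_criticality <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("FLOODED", "LOST", "DECREASED",
                                          "UNCHANGED", "BACKUP_INCREASED")))
  out <- tibble::as_tibble(as.list(tab))
  names(out) <- tolower(names(out))
  out$n_edges <- nrow(x)
  out
}

#' Tidy a node time field
#'
#' @param x a `node_time_field` from [node_access_times()].
#' @param ... unused.
#' @return A tibble `node_id`, `x`, `y`, `time_min`.
#' @method tidy node_time_field
#' @export
tidy.node_time_field <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a cell grid into long form
#'
#' @param x an `fa_grid` (friction, population or time field).
#' @param ... unused.
#' @return A tibble `x`, `y`, `row`, `col`, `value` (one row per cell).
#' @method tidy fa_grid
#' @export
tidy.fa_grid <- function(x, ...) {
  cc <- grid_cell_centers(x)
  vals <- as.vector(x$values)
  tibble::tibble(x = cc$x, y = cc$y, row = cc$row, col = cc$col, value = vals)
}

#' Summary of a pipeline run
#'
#' @param x a `pipeline_result` from [run_pipeline()].
#' @param ... unused.
#' @return A one-row tibble with the headline quantities of the run:
#'   population losing all access per engine, population with increased
#'   travel time per engine, flood-removed node and cell counts, and the
#'   peak criticality scores.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  lt_n <- x$impact$loss_table_network
  lt_r <- x$impact$loss_table_raster
  inc <- function(lt) sum(lt$population) -
    lt$population[lt$label == "NO_CHANGE"] -
    lt$population[lt$label == "LOST_ACCESS"]
  tibble::tibble(
    lost_access_network = lt_n$population[lt_n$label == "LOST_ACCESS"],
    lost_access_raster = lt_r$population[lt_r$label == "LOST_ACCESS"],
    increased_network = inc(lt_n),
    increased_raster = inc(lt_r),
    nodes_removed = x$manifest$counts$nodes_removed,
    cells_flooded = x$manifest$counts$cells_flooded,
    tebc_max_normal = max(x$tebc$normal$score),
    tebc_max_flood = max(x$tebc$flood$score),
    n_backup_edges = sum(x$tebc$delta$class == "BACKUP_INCREASED"))
}
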