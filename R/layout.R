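#' Build a two-tier pooling layout
#'
#' Plants are pooled in two tiers mirroring a 384-well screening design:
#' tier-1 pools of `tier1_size` plants (default 4), and tier-2 indexed pools
#' of `tier2_size` tier-1 pools (default 4, i.e. 16 plants share one dual
#' sequencing index). 1536 plants give 384 tier-1 and 96 tier-2 pools.
#'
#' @param n_plants number of plants; must be divisible by
#'   `tier1_size * tier2_size` unless `pad = TRUE`.
#' @param tier1_size plants per tier-1 pool.
#' @param tier2_size tier-1 pools per tier-2 pool.
#' @param plant_ids optional character vector of plant (line) ids.
#' @param pad if TRUE, the last pools may be incomplete instead of erroring.
#' @return object of class `pooling_layout`: list with `n_plants`, `tier1`
#'   (named plant -> tier-1 pool), `tier2` (named tier-1 -> tier-2 pool),
#'   `index_pairs` (NULL until [assign_indexes()]).
#' @export
build_layout <- function(n_plants, tier1_size = 4L, tier2_size = 4L,
                         plant_ids = NULL, pad = FALSE) {
  stop_if_not_scalar_pos(n_plants, "n_plants", integer = TRUE)
  stop_if_not_scalar_pos(tier1_size, "tier1_size", integer = TRUE)
  stop_if_not_scalar_pos(tier2_size, "tier2_size", integer = TRUE)
  block <- tier1_size * tier2_size
  if (n_plants %% block != 0L && !pad) {
    stop(sprintf("n_plants (%d) not divisible by tier1_size*tier2_size (%d); ",
                 n_plants, block), "set pad = TRUE to allow incomplete pools")
  }
  if (is.null(plant_ids)) plant_ids <- sprintf("L%04d", seq_len(n_plants))
  stopifnot(length(plant_ids) == n_plants, !anyDuplicated(plant_ids))

  n_t1 <- ceiling(n_plants / tier1_size)
  n_t2 <- ceiling(n_t1 / tier2_size)
  t1_ids <- sprintf("t1_%03d", seq_len(n_t1))
  t2_ids <- sprintf("pool_%02d", seq_len(n_t2))
  tier1 <- stats::setNames(t1_ids[ceiling(seq_len(n_plants) / tier1_size)], plant_ids)
  tier2 <- stats::setNames(t2_ids[ceiling(seq_len(n_t1) / tier2_size)], t1_ids)
  structure(list(n_plants = as.integer(n_plants),
                 tier1_size = as.integer(tier1_size),
                 tier2_size = as.integer(tier2_size),
                 tier1 = tier1, tier2 = tier2, index_pairs = NULL),
            class = "pooling_layout")
}

#' @export
print.pooling_layout <- function(x, ...) {
  cat(sprintf("pooling_layout: %d plants -> %d tier-1 pools -> %d indexed pools%s\n",
              x$n_plants, length(unique(x$tier1)), length(unique(x$tier2)),
              if (is.null(x$index_pairs)) "" else " (indexed)"))
  invisible(x)
}

#' Assign dual index pairs to tier-2 pools
#'
#' Deterministic row-major assignment of (i7, i5) adaptor label pairs to the
#' indexed pools; 12 i7 x 8 i5 labels cover the default 96 pools exactly.
#'
#' @param layout a `pooling_layout`.
#' @param i7_labels,i5_labels character label vectors (defaults: 12 i7, 8 i5).
#' @return the layout with `index_pairs` filled (data.frame: pool, i7, i5).
#' @export
assign_indexes <- function(layout,
                           i7_labels = sprintf("N7%02d", 1:12),
                           i5_labels = sprintf("S5%02d", 1:8)) {
  stopifnot(inherits(layout, "pooling_layout"))
  pools <- unique(layout$tier2)
  if (length(i7_labels) * length(i5_labels) < length(pools)) {
    stop(sprintf("need %d index pairs but only %d x %d = %d available",
                 length(pools), length(i7_labels), length(i5_labels),
                 length(i7_labels) * length(i5_labels)))
  }
  k <- seq_along(pools) - 1L
  layout$index_pairs <- data.frame(
    pool = pools,
    i7 = i7_labels[k %% length(i7_labels) + 1L],
    i5 = i5_labels[k %/% length(i7_labels) + 1L],
    stringsAsFactors = FALSE
  )
  layout
}

#' Pool membership of a plant, and plants of a pool
#'
#' @param layout a `pooling_layout`.
#' @param plant_id plant id.
#' @return tier-2 pool id for `pool_of_plant`; for [plants_of_pool()] a
#'   character vector of plant ids, named by their tier-1 pool.
#' @export
pool_of_plant <- function(layout, plant_id) {
  t1 <- layout$tier1[plant_id]
  if (any(is.na(t1))) stop("unknown plant id(s)")
  unname(layout$tier2[t1])
}

#' @rdname pool_of_plant
#' @param pool_id tier-2 pool id.
#' @export
plants_of_pool <- function(layout, pool_id) {
  if (!pool_id %in% layout$tier2) stop("unknown pool id: ", pool_id)
  t1s <- names(layout$tier2)[layout$tier2 == pool_id]
  plants <- names(layout$tier1)[layout$tier1 %in% t1s]
  stats::setNames(plants, layout$tier1[plants])
}

#' Convert a layout to/from its CSV table form
#'
#' @param layout a `pooling_layout`.
#' @return data.frame with columns plant_id, tier1_pool, tier2_pool, i7, i5.
#' @export
layout_table <- function(layout) {
  plants <- names(layout$tier1)
  t1 <- unname(layout$tier1)
  t2 <- unname(layout$tier2[t1])
  ip <- layout$index_pairs
  df <- data.frame(plant_id = plants, tier1_pool = t1, tier2_pool = t2,
                   stringsAsFactors = FALSE)
  if (!is.null(ip)) {
    m <- match(t2, ip$pool)
    df$i7 <- ip$i7[m]
    df$i5 <- ip$i5[m]
  }
  df
}

#' @rdname layout_table
#' @param df a data.frame as produced by [layout_table()].
#' @export
layout_from_table <- function(df) {
  need <- c("plant_id", "tier1_pool", "tier2_pool")
  if (!all(need %in% names(df))) stop("layout table needs columns: ",
                                      paste(need, collapse = ", "))
  t1_sizes <- table(df$tier1_pool)
  lay <- structure(list(
    n_plants = nrow(df),
    tier1_size = as.integer(max(t1_sizes)),
    tier2_size = as.integer(max(table(unique(df[c("tier1_pool", "tier2_pool")])$tier2_pool))),
    tier1 = stats::setNames(df$tier1_pool, df$plant_id),
    tier2 = stats::setNames(
      df$tier2_pool[!duplicated(df$tier1_pool)],
      df$tier1_pool[!duplicated(df$tier1_pool)]),
    index_pairs = NULL), class = "pooling_layout")
  if (all(c("i7", "i5") %in% names(df))) {
    u <- !duplicated(df$tier2_pool)
    lay$index_pairs <- data.frame(pool = df$tier2_pool[u], i7 = df$i7[u],
                                  i5 = df$i5[u], stringsAsFactors = FALSE)
  }
  lay
}
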