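#' Resample a raster onto a target grid
#'
#' Categorical layers use nearest-neighbour (source cell containing the
#' target cell centre); continuous layers use the area-weighted mean of
#' overlapping source cells, ignoring nodata. Both CRSs must be identical —
#' reprojection is out of scope — and the extents must overlap.
#'
#' @param layer A [categorical_raster()] or [continuous_raster()].
#' @param target Target [grid_spec()].
#' @return A raster of the same kind on `target`.
#' @export
resample_to_grid <- function(layer, target) {
  stopifnot(inherits(target, "grid_spec"))
  src <- layer$grid
  if (!identical(src$crs_id, target$crs_id))
    stop("resample_to_grid: CRS mismatch (", src$crs_id, " vs ",
         target$crs_id, "); reprojection is out of scope")
  sx0 <- src$origin_x; sx1 <- src$origin_x + src$n_cols * src$cell_size
  sy1 <- src$origin_y; sy0 <- src$origin_y - src$n_rows * src$cell_size
  tx0 <- target$origin_x; tx1 <- target$origin_x + target$n_cols * target$cell_size
  ty1 <- target$origin_y; ty0 <- target$origin_y - target$n_rows * target$cell_size
  if (tx1 <= sx0 || tx0 >= sx1 || ty1 <= sy0 || ty0 >= sy1)
    stop("resample_to_grid: extents do not overlap")

  if (inherits(layer, "categorical_raster")) {
    cc <- cell_centres(target)
    sc <- floor((cc$x - sx0) / src$cell_size) + 1L
    sr <- floor((sy1 - cc$y) / src$cell_size) + 1L
    out <- matrix(layer$nodata_code, target$n_rows, target$n_cols)
    ok <- sr >= 1L & sr <= src$n_rows & sc >= 1L & sc <= src$n_cols
    out[ok] <- layer$codes[cbind(sr[ok], sc[ok])]
    return(categorical_raster(target, out, layer$legend, layer$nodata_code))
  }
  if (!inherits(layer, "continuous_raster"))
    stop("resample_to_grid: not a raster object")

  # 1-D interval-overlap weights, separable in x and y
  overlap_1d <- function(t_lo, t_hi, s_lo, s_hi) {
    # rows: target intervals, cols: source intervals
    lo <- outer(t_lo, s_lo, pmax)
    hi <- outer(t_hi, s_hi, pmin)
    w <- hi - lo
    w[w < 0] <- 0
    w
  }
  tx <- tx0 + (0:target$n_cols) * target$cell_size
  ty <- ty1 - (0:target$n_rows) * target$cell_size  # descending
  sxv <- sx0 + (0:src$n_cols) * src$cell_size
  syv <- sy1 - (0:src$n_rows) * src$cell_size
  Wc <- overlap_1d(head(tx, -1), tail(tx, -1), head(sxv, -1), tail(sxv, -1))
  Wr <- overlap_1d(rev(tail(ty, -1)), rev(head(ty, -1)),
                   rev(tail(syv, -1)), rev(head(syv, -1)))
  # undo the reversal used to make intervals ascending
  Wr <- Wr[rev(seq_len(nrow(Wr))), rev(seq_len(ncol(Wr))), drop = FALSE]
  v <- layer$values
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  num <- Wr %*% v0 %*% t(Wc)
  den <- Wr %*% (ok * 1) %*% t(Wc)
  out <- ifelse(den > 0, num / den, NA_real_)
  continuous_raster(target, out, layer$nodata_sentinel)
}
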