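#' Production-share-weighted factor for untraced volume
#'
#' Exported tonnage whose production department is unknown is priced at
#' the average department factor weighted by each department's untraced
#' volume, `u_d = max(0, production_d - traced volume_d)` — the only
#' mass-consistent reconstruction from the available fields. If no volume
#' is untraced the plain production-weighted factor is returned with a
#' warning.
#'
#' @param dept_table [department_aggregate()] output.
#' @param trade Trade table (`department_id`, `exporter`, `importer`,
#'   `volume_t`).
#' @param bf_column Which department factor to weight: `"bf_all"`
#'   (cell-mean, default) or `"bf_weighted"` (production-weighted).
#' @return Scalar factor (ha yr t^-1).
#' @export
untraced_bf <- function(dept_table, trade, bf_column = c("bf_all", "bf_weighted")) {
  bf_column <- match.arg(bf_column)
  dt <- data.table::as.data.table(trade)
  traced <- dt[department_id != "UNKNOWN",
               .(traced_t = sum(volume_t)), by = .(department_id)]
  tab <- data.table::as.data.table(dept_table)
  tab[, dept_chr := as.character(department_id)]
  tab <- merge(tab, traced, by.x = "dept_chr", by.y = "department_id",
               all.x = TRUE)
  tab[is.na(traced_t), traced_t := 0]
  tab[, untraced_t := pmax(0, production_t - traced_t)]
  has_unknown <- nrow(dt[department_id == "UNKNOWN" & volume_t > 0]) > 0
  bf <- tab[[bf_column]]
  usable <- !is.na(bf)
  if (sum(tab$untraced_t[usable]) <= 0) {
    if (has_unknown)
      stop("untraced_bf: UNKNOWN rows present but no department has ",
           "untraced volume (mass imbalance)")
    warning("untraced_bf: all volume traced; returning production-weighted factor")
    w <- tab$production_t[usable]
    return(sum(w * bf[usable]) / sum(w))
  }
  w <- tab$untraced_t[usable]
  sum(w * bf[usable]) / sum(w)
}

#' Attribute biodiversity impacts to trade flows
#'
#' Traced rows get `bim = volume * BF_department`; `UNKNOWN` rows get
#' `bim = volume * untraced_bf(...)`.
#'
#' @param trade Trade table.
#' @param dept_table [department_aggregate()] output covering every
#'   department referenced by `trade`.
#' @param bf_column Factor variant, as in [untraced_bf()].
#' @return `data.table`: trade columns plus `bim` (ha yr) and
#'   `traced_flag`.
#' @export
attribute_flows <- function(trade, dept_table,
                            bf_column = c("bf_all", "bf_weighted")) {
  bf_column <- match.arg(bf_column)
  dt <- data.table::as.data.table(trade)
  tab <- data.table::as.data.table(dept_table)
  if (any(dt$volume_t < 0)) stop("attribute_flows: negative volume")
  known <- unique(dt$department_id[dt$department_id != "UNKNOWN"])
  missing_d <- setdiff(known, as.character(tab$department_id))
  if (length(missing_d))
    stop("attribute_flows: unknown department id(s): ",
         paste(missing_d, collapse = ", "))
  bf_map <- setNames(tab[[bf_column]], as.character(tab$department_id))
  out <- data.table::copy(dt)
  out[, traced_flag := department_id != "UNKNOWN"]
  out[traced_flag == TRUE, bim := volume_t * bf_map[department_id]]
  if (any(!out$traced_flag)) {
    ubf <- untraced_bf(dept_table, trade, bf_column)
    out[traced_flag == FALSE, bim := volume_t * ubf]
  }
  if (anyNA(out$bim))
    stop("attribute_flows: a flow references a department without a factor ",
         "(no cocoa cells)")
  bf_audit("attribute_flows", flow_t = sum(out$volume_t),
           bim_ha_yr = sum(out$bim))
  out[]
}

#' Aggregate attributed flows by exporter or importer
#'
#' Importer aggregation excludes `DOMESTIC` rows (domestic consumption,
#' processing and stocks carry impacts but are not imports). Also reports
#' each actor's traced impact share and, in the attributes, the export
#' share of total impacts.
#'
#' @param actor `"exporter"` or `"importer"`.
#' @param flows [attribute_flows()] output.
#' @return `data.table`: `actor`, `volume_t`, `bim`, `bf_per_ton`
#'   (`NA` for zero-volume actors), `traced_share`. Attributes:
#'   `export_share_of_impacts`.
#' @export
aggregate_by <- function(actor = c("exporter", "importer"), flows) {
  actor <- match.arg(actor)
  fl <- data.table::as.data.table(flows)
  if (!nrow(fl)) stop("aggregate_by: empty flow table")
  total_bim <- sum(fl$bim)
  export_bim <- sum(fl$bim[fl$importer != "DOMESTIC"])
  if (actor == "importer") fl <- fl[importer != "DOMESTIC"]
  fl[, key_ := if (actor == "exporter") exporter else importer]
  res <- fl[, .(volume_t = sum(volume_t), bim = sum(bim),
                traced_bim = sum(bim[traced_flag])), by = .(key_)]
  res[, bf_per_ton := ifelse(volume_t > 0, bim / volume_t, NA_real_)]
  res[, traced_share := ifelse(bim > 0, traced_bim / bim, NA_real_)]
  res[, traced_bim := NULL]
  data.table::setnames(res, "key_", actor)
  data.table::setorder(res, -bim)
  data.table::setattr(res, "export_share_of_impacts",
                      if (total_bim > 0) export_bim / total_bim else NA_real_)
  res[]
}

#' Traceability ratios of a flow table
#'
#' The production-basis ratio (untraced volume over total production) and
#' the export-basis ratio (traced export volume over total exports) are
#' both reported, since either denominator is meaningful.
#'
#' @param flows Attributed or raw trade table.
#' @param total_production National production (t).
#' @return List: `untraced_share_of_production`,
#'   `traced_share_of_exports`.
#' @export
traceability_ratios <- function(flows, total_production) {
  fl <- data.table::as.data.table(flows)
  unk <- sum(fl$volume_t[fl$department_id == "UNKNOWN"])
  exp_t <- sum(fl$volume_t[fl$importer != "DOMESTIC"])
  list(untraced_share_of_production = unk / total_production,
       traced_share_of_exports = if (exp_t > 0) 1 - unk / exp_t else NA_real_)
}
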