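#' Run the full biodiversity-footprint pipeline
#'
#' Executes the stages synth -> harmonize -> msa -> importance -> impact ->
#' trade from one configuration, writing every stage's outputs under
#' `outdir` and a machine-readable `run_summary.json` (paths, md5
#' checksums, national totals, seed, config hash). Re-running with the same
#' config and seed reproduces identical checksums. With `resume = TRUE`, a
#' stage whose outputs already exist under an identical config hash is
#' reloaded from disk instead of recomputed.
#'
#' @param config Path to a JSON config file, or a config list from
#'   [load_config()].
#' @param outdir Output directory (created if needed).
#' @param resume Reuse cached stage outputs when the config hash matches.
#' @return Invisibly, a list with `summary` (the run summary) and
#'   `results` (in-memory stage objects).
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("biofoot_run_"),
                         resume = FALSE) {
  cfg <- if (is.character(config)) load_config(config)
         else if (is.null(config)) load_config()
         else validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  hash_file <- file.path(outdir, "config.md5")
  writeLines(as.character(cfg_json), file.path(outdir, "config.json"))
  cfg_hash <- unname(tools::md5sum(file.path(outdir, "config.json")))
  cache_ok <- resume && file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE)[1], cfg_hash)
  writeLines(cfg_hash, hash_file)
  grid <- grid_spec(cfg$n_rows, cfg$n_cols, cfg$cell_size, crs_id = cfg$crs_id)
  res <- new.env(parent = emptyenv())
  stages <- list()
  pth <- function(...) file.path(outdir, ...)
  run_stage <- function(name, outputs, compute, load) {
    t0 <- Sys.time()
    if (cache_ok && all(file.exists(pth(outputs)))) {
      bf_log("info", "stage %s: cached", name)
      load()
    } else {
      ok <- tryCatch({ compute(); TRUE },
                     error = function(e) {
                       stop("stage '", name, "' failed: ", conditionMessage(e),
                            call. = FALSE)
                     })
    }
    sums <- tools::md5sum(pth(outputs))
    names(sums) <- basename(names(sums))
    stages[[name]] <<- list(
      outputs = outputs,
      checksums = as.list(sums),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    invisible(NULL)
  }

  # ---- synth -------------------------------------------------------------
  bundle_rasters <- c("base_landcover", "cocoa_presence", "cocoa_shade_hint",
                      "forest_management", "forest_integrity",
                      "livestock_density", "pnv", "suitability", "dem")
  synth_out <- c(paste0(bundle_rasters, ".asc"), "roads.geojson",
                 "departments.geojson", "species.geojson")
  run_stage("synth", synth_out,
    compute = function() {
      b <- generate_landscape(stage_seed(cfg$seed, "synth"), grid,
                              cfg$class_mix,
                              n_departments = cfg$n_departments)
      for (nm in bundle_rasters) write_raster(b[[nm]], pth(paste0(nm, ".asc")))
      write_roads_geojson(b$roads, pth("roads.geojson"), grid$crs_id)
      write_polygons_geojson(b$departments, pth("departments.geojson"),
                             grid$crs_id)
      sp <- generate_species(stage_seed(cfg$seed, "species"), cfg$n_species,
                             grid, b$dem)
      write_species_geojson(sp, grid, pth("species.geojson"))
      res$bundle <- b; res$species <- sp
    },
    load = function() {
      b <- list()
      kinds <- c(base_landcover = "categorical", cocoa_presence = "categorical",
                 cocoa_shade_hint = "categorical",
                 forest_management = "categorical",
                 forest_integrity = "continuous",
                 livestock_density = "continuous", pnv = "categorical",
                 suitability = "continuous", dem = "continuous")
      for (nm in bundle_rasters)
        b[[nm]] <- read_raster(pth(paste0(nm, ".asc")), kinds[[nm]])
      b$roads <- read_roads_geojson(pth("roads.geojson"))
      b$departments <- read_polygons_geojson(pth("departments.geojson"))
      res$bundle <- structure(b, class = "landscape_bundle")
      res$species <- read_species_geojson(pth("species.geojson"), grid)
    })

  # ---- harmonize ---------------------------------------------------------
  harm_out <- c("landuse.asc", "cocoa_mask.asc", "cocoa_type.asc")
  run_stage("harmonize", harm_out,
    compute = function() {
      lu <- harmonize(res$bundle, cfg)
      write_raster(lu, pth("landuse.asc"))
      write_raster(categorical_raster(grid, lu$cocoa_mask,
                                      c(absent = 0L, present = 1L)),
                   pth("cocoa_mask.asc"))
      write_raster(categorical_raster(grid, lu$cocoa_type_mask,
                                      c(full_sun = 1L, agroforestry = 2L)),
                   pth("cocoa_type.asc"))
      res$landuse <- lu
    },
    load = function() {
      lur <- read_raster(pth("landuse.asc"), "categorical")
      cm <- read_raster(pth("cocoa_mask.asc"), "categorical")
      ct <- read_raster(pth("cocoa_type.asc"), "categorical")
      res$landuse <- landuse_raster(grid, lur$codes, cm$codes, ct$codes)
    })

  # ---- msa ---------------------------------------------------------------
  params <- default_msa_params()
  msa_out <- c("msa_lu.asc", "msa_infra.asc", "msa_frag.asc", "msa_total.asc",
               "msa_loss.asc", "msa_summary.json")
  run_stage("msa", msa_out,
    compute = function() {
      lr <- msa_loss_cocoa(res$landuse, res$bundle$roads, params)
      for (nm in c("msa_lu", "msa_infra", "msa_frag", "msa_total"))
        write_raster(lr$msa[[nm]], pth(paste0(nm, ".asc")))
      write_raster(lr$loss, pth("msa_loss.asc"))
      mt <- lr$msa$msa_total$values
      jsonlite::write_json(
        list(area_weighted_mean_msa = mean(mt, na.rm = TRUE),
             n_clamped_negative_loss = lr$n_clamped),
        pth("msa_summary.json"), auto_unbox = TRUE, digits = NA)
      res$msa <- lr
    },
    load = function() {
      layer_names <- c("msa_lu", "msa_infra", "msa_frag", "msa_total")
      res$msa <- list(
        msa = lapply(setNames(layer_names, layer_names),
                     function(x) read_raster(pth(paste0(x, ".asc")),
                                             "continuous")),
        loss = read_raster(pth("msa_loss.asc"), "continuous"))
    })

  # ---- importance --------------------------------------------------------
  run_stage("importance", c("rwr_aggregated.asc", "ri.asc"),
    compute = function() {
      rwr <- aggregate_rwr(lapply(res$species, species_rwr,
                                  dem = res$bundle$dem, grid = grid))
      ri <- rwr_to_ri(rwr, cfg$ri_floor)
      write_raster(rwr, pth("rwr_aggregated.asc"))
      write_raster(ri, pth("ri.asc"))
      res$rwr <- rwr; res$ri <- ri
    },
    load = function() {
      res$rwr <- read_raster(pth("rwr_aggregated.asc"), "continuous")
      res$ri <- read_raster(pth("ri.asc"), "continuous")
    })

  # ---- impact ------------------------------------------------------------
  impact_out <- c("yield.asc", "bim_total.asc", "bim_cocoa.asc", "bf.asc",
                  "department_impacts.csv")
  has_cocoa <- sum(res$landuse$cocoa_mask) > 0
  run_stage("impact", if (has_cocoa) impact_out else impact_out[c(2)],
    compute = function() {
      bt <- bim_total(res$msa$msa$msa_total, res$ri, grid)
      write_raster(bt$raster, pth("bim_total.asc"))
      res$bim_total <- bt
      if (!has_cocoa) {
        bf_log("warn", "impact: no cocoa cells; cocoa metrics skipped")
        return(invisible(NULL))
      }
      y <- downscale_yield(res$bundle$suitability, res$landuse$cocoa_mask,
                           cfg$national_production, cfg$occupation_years)
      bc <- bim_cocoa(res$msa$loss, res$ri, res$landuse$cocoa_mask, grid)
      bfr <- bf_cocoa(bc$raster, y, res$landuse$cocoa_mask,
                      cfg$occupation_years)
      dep <- rasterize_polygons(res$bundle$departments, grid)
      tab <- department_aggregate(dep, y, bfr, bc$raster, bt$raster,
                                  res$landuse$cocoa_mask,
                                  res$landuse$cocoa_type_mask,
                                  cfg$occupation_years)
      write_raster(y, pth("yield.asc"))
      write_raster(bc$raster, pth("bim_cocoa.asc"))
      write_raster(bfr, pth("bf.asc"))
      write_table_csv(tab, pth("department_impacts.csv"))
      res$yield <- y; res$bim_cocoa <- bc; res$bf <- bfr
      res$departments_raster <- dep; res$dept_table <- tab
    },
    load = function() {
      res$bim_total <- list(
        raster = read_raster(pth("bim_total.asc"), "continuous"))
      res$bim_total$total <- sum(res$bim_total$raster$values, na.rm = TRUE)
      if (has_cocoa) {
        res$yield <- read_raster(pth("yield.asc"), "continuous")
        bc <- read_raster(pth("bim_cocoa.asc"), "continuous")
        res$bim_cocoa <- list(raster = bc,
                              total = sum(bc$values, na.rm = TRUE))
        res$bf <- read_raster(pth("bf.asc"), "continuous")
        res$dept_table <- read_table_csv(pth("department_impacts.csv"))
      }
    })

  # ---- trade -------------------------------------------------------------
  trade_skipped <- !has_cocoa
  if (trade_skipped) {
    bf_log("warn", "trade: skipped, landscape has no cocoa")
  } else {
    trade_out <- c("trade.csv", "flows.csv", "exporters.csv", "importers.csv",
                   "sankey_edges.csv")
    run_stage("trade", trade_out,
      compute = function() {
        prod_vec <- setNames(res$dept_table$production_t,
                             as.character(res$dept_table$department_id))
        prod_vec <- prod_vec[prod_vec > 0]
        trade <- generate_trade(stage_seed(cfg$seed, "trade"), prod_vec,
                                list(n_exporters = cfg$n_exporters,
                                     n_importers = cfg$n_importers,
                                     untraced_fraction = cfg$untraced_fraction,
                                     export_fraction = cfg$export_fraction))
        flows <- attribute_flows(trade, res$dept_table)
        write_table_csv(trade, pth("trade.csv"))
        write_table_csv(flows, pth("flows.csv"))
        write_table_csv(aggregate_by("exporter", flows), pth("exporters.csv"))
        write_table_csv(aggregate_by("importer", flows), pth("importers.csv"))
        write_table_csv(flows[, .(source = exporter, target = importer, bim)],
                        pth("sankey_edges.csv"))
        res$trade <- trade; res$flows <- flows
      },
      load = function() {
        res$trade <- read_table_csv(pth("trade.csv"))
        res$flows <- read_table_csv(pth("flows.csv"))
      })
  }

  # ---- summary -----------------------------------------------------------
  national <- list(bim_total = res$bim_total$total)
  if (has_cocoa) {
    cm <- res$landuse$cocoa_mask == 1L
    cocoa_area_bt <- sum(res$bim_total$raster$values[cm], na.rm = TRUE)
    national$bim_cocoa <- res$bim_cocoa$total
    national$cocoa_share_of_cocoa_area_impacts <-
      if (cocoa_area_bt > 0) res$bim_cocoa$total / cocoa_area_bt else NA_real_
    exp_bim <- sum(res$flows$bim[res$flows$importer != "DOMESTIC"])
    national$export_share_of_cocoa_impacts <- exp_bim / sum(res$flows$bim)
  } else {
    national$bim_cocoa <- 0
  }
  summary <- list(seed = cfg$seed, config_hash = cfg_hash,
                  trade_skipped = trade_skipped,
                  national = national, stages = stages)
  jsonlite::write_json(summary, pth("run_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(summary = summary, results = res, outdir = outdir))
}
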