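# Result tables, serialization and the summary figure.

#' Run the complete experiment set
#'
#' Runs the single-cell and cluster simulations for both embedded
#' radionuclides and all four source distributions, returning tidy result
#' tables from which the summary tables and figure are rendered.
#'
#' @param nDecays decays per single-cell run.
#' @param clusterDecays sampled decays per source distance class in the
#'   cluster runs (expected-value scoring makes the per-class variance
#'   small, so this can be well below `nDecays`).
#' @param nBatches statistical batches.
#' @param seed base RNG seed; each run derives its own sub-seed.
#' @param cell the \linkS4class{CellModel} phantom.
#' @param pitch cluster lattice pitch in um.
#' @param energyDensity released energy per unit volume in MeV/um3.
#' @param verbose emit per-run progress messages.
#' @return list with elements `single` and `cluster`, both `data.frame`s
#'   with one row per radionuclide and distribution (and, for the
#'   cluster, target).
#' @export
runFullStudy <- function(nDecays = 1e6, clusterDecays = 2e5, nBatches = 20,
                         seed = 1, cell = cellModel(),
                         pitch = 2 * cell@cellRadius, energyDensity = 1,
                         verbose = interactive()) {
  nucs <- lapply(listRadionuclides(), radionuclide)
  names(nucs) <- listRadionuclides()
  singles <- list(); clusters <- list()
  runSeed <- seed
  for (nm in names(nucs)) {
    for (dist in sourceDistributions()) {
      runSeed <- runSeed + 1
      if (verbose) message("single cell: ", nm, " / ", dist)
      cfg <- runConfig(nucs[[nm]], dist, nDecays = nDecays,
                       nBatches = nBatches, seed = runSeed,
                       energyDensity = energyDensity, cell = cell)
      rep <- runSingleCell(cfg)
      singles[[length(singles) + 1L]] <- cbind(
        data.frame(radionuclide = nm, distribution = dist), rep@results)
      runSeed <- runSeed + 1
      if (verbose) message("cluster: ", nm, " / ", dist)
      ccfg <- runConfig(nucs[[nm]], dist, nDecays = clusterDecays,
                        nBatches = nBatches, seed = runSeed,
                        energyDensity = energyDensity, cell = cell)
      crep <- runCluster(ccfg, pitch = pitch)
      clusters[[length(clusters) + 1L]] <- cbind(
        data.frame(radionuclide = nm, distribution = dist), crep@results)
    }
  }
  list(single = do.call(rbind, singles), cluster = do.call(rbind, clusters))
}

.distOrder <- function() sourceDistributions()

.pivotDose <- function(df, value = "dose_Gy") {
  dists <- .distOrder()
  nucs <- unique(df$radionuclide)
  out <- as.data.frame(matrix(NA_real_, length(nucs), length(dists),
                              dimnames = list(NULL, dists)))
  for (i in seq_along(nucs)) for (j in seq_along(dists)) {
    v <- df[[value]][df$radionuclide == nucs[i] & df$distribution == dists[j]]
    if (length(v)) out[i, j] <- v
  }
  cbind(data.frame(radionuclide = nucs), out)
}

.enhancementRow <- function(wide, digits = 1) {
  lu <- unlist(wide[wide$radionuclide == "lu177", -1])
  tb <- unlist(wide[wide$radionuclide == "tb161", -1])
  round(enhancementFactor(tb, lu), digits)
}

#' Render the summary tables
#'
#' Writes three CSV files mirroring the layout of the result tables:
#' `table2.csv` (single-cell nucleus doses per distribution plus the
#' 161Tb/177Lu enhancement factor, 1 decimal), `table3.csv` (cluster
#' central-cell doses formatted `dose (self%)` plus the enhancement
#' factor) and `table4.csv` (first/second-neighbourhood totals and
#' integer self-dose percentages).  Raw unrounded values belong in the
#' JSON output ([writeResults()]).
#'
#' @param results result list from [runFullStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths of the files written.
#' @export
renderTables <- function(results, dir = ".") {
  if (is.null(results$single) || nrow(results$single) == 0L)
    stop("empty results: nothing to render")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  # single cell
  w <- .pivotDose(results$single)
  if (anyNA(w)) stop("missing single-cell result cells; run all configurations")
  t2 <- rbind(
    cbind(w[1], as.data.frame(round(as.matrix(w[-1]), 1))),
    data.frame(radionuclide = "enhancement_tb161_lu177",
               t(.enhancementRow(w))))
  p <- file.path(dir, "table2.csv")
  utils::write.csv(t2, p, row.names = FALSE)
  paths <- c(paths, p)

  # cluster central with self-dose percentage in parentheses
  cen <- results$cluster[results$cluster$target == "central", ]
  if (nrow(cen) == 0L) stop("missing cluster central-cell results")
  wd <- .pivotDose(cen)
  wp <- .pivotDose(cen, "self_pct")
  fmt <- wd
  for (j in seq_along(.distOrder()) + 1L)
    fmt[[j]] <- sprintf("%.1f (%d%%)", wd[[j]], as.integer(round(wp[[j]])))
  er <- as.data.frame(t(.enhancementRow(wd)))
  er[] <- lapply(er, as.character)
  t3 <- rbind(fmt, cbind(data.frame(radionuclide = "enhancement_tb161_lu177"),
                         er))
  p <- file.path(dir, "table3.csv")
  utils::write.csv(t3, p, row.names = FALSE)
  paths <- c(paths, p)

  # neighbourhood cells
  nb <- results$cluster[results$cluster$target %in% c("n1", "n2"), ]
  if (nrow(nb) == 0L) stop("missing neighbourhood results")
  rows <- list()
  for (nm in unique(nb$radionuclide)) {
    for (what in c("total_dose_Gy", "self_pct")) {
      vals <- lapply(.distOrder(), function(d) {
        v1 <- nb[nb$radionuclide == nm & nb$distribution == d & nb$target == "n1", ]
        v2 <- nb[nb$radionuclide == nm & nb$distribution == d & nb$target == "n2", ]
        if (what == "total_dose_Gy")
          c(round(v1$dose_Gy, 1), round(v2$dose_Gy, 1))
        else c(as.integer(round(v1$self_pct)), as.integer(round(v2$self_pct)))
      })
      row <- data.frame(radionuclide = nm, quantity = what)
      for (k in seq_along(.distOrder())) {
        row[[paste0(.distOrder()[k], "_n1")]] <- vals[[k]][1]
        row[[paste0(.distOrder()[k], "_n2")]] <- vals[[k]][2]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  t4 <- do.call(rbind, rows)
  p <- file.path(dir, "table4.csv")
  utils::write.csv(t4, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Serialize results to CSV and JSON
#'
#' Writes `results.csv` (one row per nuclide, distribution and target:
#' dose, self, cross, self percentage, SEM) and `results.json` carrying
#' the same values at full double precision plus a configuration echo, so
#' the JSON round-trips bit-exactly.
#'
#' @param results result list from [runFullStudy()], or a single
#'   \linkS4class{DoseReport}.
#' @param dir output directory.
#' @param configEcho optional list echoed under `$config` in the JSON.
#' @return invisibly, the paths written.
#' @export
writeResults <- function(results, dir = ".", configEcho = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is(results, "DoseReport")) {
    configEcho <- results@config
    results <- list(report = cbind(
      data.frame(radionuclide = results@radionuclide,
                 distribution = results@distribution,
                 geometry = results@geometry), results@results))
  }
  flat <- do.call(rbind, lapply(names(results), function(nm) {
    df <- results[[nm]]
    df$geometry <- if ("geometry" %in% names(df)) df$geometry else nm
    df
  }))
  csv <- file.path(dir, "results.csv")
  utils::write.csv(flat, csv, row.names = FALSE)
  json <- file.path(dir, "results.json")
  # 17 significant digits: doubles round-trip bit-exactly through decimal
  jsonlite::write_json(list(config = configEcho, results = results),
                       json, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(c(csv, json))
}

#' Read results back from JSON
#'
#' @param path path to a `results.json` written by [writeResults()].
#' @return list with `config` and `results` (data.frames).
#' @export
readResults <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$results <- lapply(x$results, as.data.frame)
  x
}

#' Summary figure: grouped bars of nucleus doses
#'
#' Absorbed dose to the nucleus of the single cell and of the cluster's
#' central cell, grouped by source distribution, one bar per
#' radionuclide.
#'
#' @param results result list from [runFullStudy()].
#' @return a ggplot object.
#' @export
doseFigure <- function(results) {
  cen <- results$cluster[results$cluster$target == "central", ]
  df <- rbind(cbind(results$single[c("radionuclide", "distribution", "dose_Gy")],
                    geometry = "single cell"),
              cbind(cen[c("radionuclide", "distribution", "dose_Gy")],
                    geometry = "cluster central cell"))
  df$distribution <- factor(df$distribution, levels = .distOrder())
  df$geometry <- factor(df$geometry,
                        levels = c("single cell", "cluster central cell"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distribution, y = .data$dose_Gy,
                                   fill = .data$radionuclide)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~geometry) +
    ggplot2::labs(x = "source distribution",
                  y = "absorbed dose to nucleus (Gy)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
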