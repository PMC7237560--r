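#' Accessors for dose reports
#'
#' Extract the absorbed dose, self-dose, cross-dose, self-dose percentage
#' or batch standard error from a \linkS4class{DoseReport}.  All return a named
#' numeric vector, one element per target.
#'
#' @param object a \linkS4class{DoseReport}.
#' @return named numeric vector (names are the target labels).
#' @examples
#' cfg <- runConfig(radionuclide("lu177"), "nucleus", nDecays = 2000, seed = 1)
#' rep <- runSingleCell(cfg)
#' doseGy(rep)
#' selfFraction(rep)
#' @export
setGeneric("doseGy", function(object) standardGeneric("doseGy"))

#' @rdname doseGy
#' @export
setGeneric("selfDoseGy", function(object) standardGeneric("selfDoseGy"))

#' @rdname doseGy
#' @export
setGeneric("crossDoseGy", function(object) standardGeneric("crossDoseGy"))

#' @rdname doseGy
#' @export
setGeneric("selfFraction", function(object) standardGeneric("selfFraction"))

#' @rdname doseGy
#' @export
setGeneric("semGy", function(object) standardGeneric("semGy"))

.named <- function(report, col) {
  out <- report@results[[col]]
  names(out) <- report@results$target
  out
}

#' @rdname doseGy
setMethod("doseGy", "DoseReport", function(object) .named(object, "dose_Gy"))

#' @rdname doseGy
setMethod("selfDoseGy", "DoseReport", function(object) .named(object, "self_Gy"))

#' @rdname doseGy
setMethod("crossDoseGy", "DoseReport", function(object) .named(object, "cross_Gy"))

#' @rdname doseGy
setMethod("selfFraction", "DoseReport", function(object) .named(object, "self_pct"))

#' @rdname doseGy
setMethod("semGy", "DoseReport", function(object) .named(object, "sem_Gy"))

setMethod("show", "RadionuclideData", function(object) {
  ln <- object@lines
  cat("RadionuclideData:", object@name, "\n")
  cat("  half-life:", object@halfLifeDays, "days (metadata only)\n")
  cat("  beta branches:", nrow(object@betaBranches),
      sprintf("(mean %.1f keV, ref %.1f keV)\n",
              sum(object@betaBranches$fraction *
                    vapply(object@spectra, `[[`, 0, "mean")),
              object@meanBetaEnergyRef))
  for (k in c("CE", "AE")) {
    sel <- ln$kind == k
    cat(sprintf("  %s lines: %d (%.2f keV/decay, ref %.2f)\n", k, sum(sel),
                sum(ln$energy_keV[sel] * ln$yield[sel]),
                if (k == "CE") object@ceEnergyPerDecayRef else object@aeEnergyPerDecayRef))
  }
  cat(sprintf("  total electron energy per decay: %.1f keV (ref %.1f)\n",
              meanEnergyPerDecay(object), object@totalElectronEnergyRef))
})

setMethod("show", "CellModel", function(object) {
  cat(sprintf(
    "CellModel: cell r=%g um, nucleus r=%g um, membrane %g um, centre (%g, %g, %g)\n",
    object@cellRadius, object@nucleusRadius, object@membraneThickness,
    object@center[1], object@center[2], object@center[3]))
  cat(sprintf("  volumes (um3): cell %.1f, nucleus %.1f, cytoplasm %.1f\n",
              cellVolume(object), nucleusVolume(object), cytoplasmVolume(object)))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d cells, pitch %g um (1 central, %d n1, %d n2)\n",
              length(object@cells), object@pitch,
              sum(object@neighbourhood == "n1"),
              sum(object@neighbourhood == "n2")))
})

setMethod("show", "SpherePhantom", function(object) {
  cat(sprintf("SpherePhantom: radius %g um, density %g g/cm3\n",
              object@radius, object@density))
})

setMethod("show", "StoppingPowerTable", function(object) {
  cat(sprintf("StoppingPowerTable: %d points, %g-%g keV, S(%g keV) = %.3f keV/um\n",
              length(object@energy), min(object@energy), max(object@energy),
              100, stoppingPower(object, 100)))
})

setMethod("show", "TransportKernel", function(object) {
  cat(sprintf(
    "TransportKernel: %d energies (%g-%g keV) x %d radii (%g-%g um)\n",
    length(object@energyGrid), min(object@energyGrid), max(object@energyGrid),
    length(object@radiusGrid), min(object@radiusGrid), max(object@radiusGrid)))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: %s, %s source, %g decays in %d batches, seed %d, %s transport\n",
    object@radionuclide@name, object@distribution, object@nDecays,
    as.integer(object@nBatches), as.integer(object@seed),
    object@transport$mode))
})

setMethod("show", "DoseReport", function(object) {
  cat(sprintf("DoseReport: %s, %s, %s\n", object@geometry,
              object@radionuclide, object@distribution))
  print(format(object@results, digits = 4), row.names = FALSE)
})
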