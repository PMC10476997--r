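## Readers/writers: NIfTI grids, spot-list CSV + plan JSON, calibration
## tables, run configuration.

PLAN_SCHEMA <- "rowdplan-plan/1"
MANIFEST_SCHEMA <- "rowdplan-manifest/1"

#' Read a 3-D grid from NIfTI
#'
#' Accepts single-component 3-D volumes; world units are mm and the axis
#' convention is RAS with the grid origin at the first voxel center.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [VoxelGrid-class].
#' @export
readGrid <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("unsupported format: expected a 3-D single-component volume, got ",
         length(d), "-D")
  m <- RNifti::xform(img)
  voxelGrid(array(as.numeric(img), d), spacing = RNifti::pixdim(img)[1:3],
            origin = m[1:3, 4])
}

#' Write a grid to NIfTI
#'
#' Values are stored as 32-bit float; spacing and origin are carried in
#' the qform/sform (RAS, mm).
#'
#' @param grid a [VoxelGrid-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeGrid <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  img <- RNifti::asNifti(grid@values)
  RNifti::pixdim(img) <- grid@spacing
  m <- diag(c(grid@spacing, 1))
  m[1:3, 4] <- grid@origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write / read a treatment plan
#'
#' A plan is stored as a spot-list CSV (columns `field_id`, `range_mm`,
#' `x_mm`, `y_mm`, `weight`) plus a JSON header with a schema tag, the
#' prescription and the field descriptions.
#'
#' @param plan a [ProtonPlan-class].
#' @param csvPath spot-list CSV path.
#' @param jsonPath plan JSON path.
#' @return `writePlan`: the paths, invisibly. `readPlan`: a
#'   [ProtonPlan-class].
#' @export
writePlan <- function(plan, csvPath, jsonPath) {
  stopifnot(is(plan, "ProtonPlan"))
  utils::write.csv(plan@spots, csvPath, row.names = FALSE)
  header <- list(schema = PLAN_SCHEMA,
                 prescription = plan@prescription,
                 fields = lapply(unname(plan@fields), function(f)
                   f[c("id", "direction", "spotSpacing", "layerSpacing")]))
  jsonlite::write_json(header, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csvPath, jsonPath))
}

#' @rdname writePlan
#' @export
readPlan <- function(csvPath, jsonPath) {
  spots <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("field_id", "range_mm", "x_mm", "y_mm", "weight")
  missing <- setdiff(need, names(spots))
  if (length(missing))
    stop("validation error: spot list lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(spots$weight < 0))
    stop("validation error: negative spot weight in ", csvPath)
  header <- jsonlite::fromJSON(jsonPath, simplifyVector = FALSE)
  if (is.null(header$schema) || !identical(header$schema, PLAN_SCHEMA))
    stop("validation error: missing or unknown plan schema tag in ", jsonPath)
  if (is.null(header$prescription))
    stop("validation error: plan header lacks 'prescription'")
  fields <- lapply(header$fields, function(f)
    beamField(f$id, f$direction, f$spotSpacing, f$layerSpacing))
  names(fields) <- vapply(fields, `[[`, "", "id")
  protonPlan(spots[need], fields, header$prescription)
}

#' Read an uptake-to-pO2 calibration table
#'
#' @param path CSV with columns uptake and pO2 (mmHg); uptake must be
#'   strictly increasing.
#' @return data.frame with columns `uptake`, `po2_mmHg`.
#' @export
readCalibration <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L)
    stop("validation error: calibration table needs two columns")
  out <- data.frame(uptake = as.numeric(tab[[1]]),
                    po2_mmHg = as.numeric(tab[[2]]))
  if (anyNA(out)) stop("validation error: non-numeric calibration entries")
  if (any(diff(out$uptake) <= 0))
    stop("configuration error: calibration uptake values must be strictly increasing")
  out
}

.CONFIG_KEYS <- c("paths", "model", "oer", "oerParams", "tissues",
                  "optimizer", "beam", "phantom", "synthetic",
                  "prescription", "seed")

#' Read a run configuration
#'
#' Strict JSON run configuration: unknown top-level keys are rejected, and
#' every command writes a resolved-config echo into its output manifest.
#' Recognized keys: `paths` (named input/output file paths), `model`
#' (plan label: rbe11, rbe11_oer, mcn_oer, ror_oer), `oer` (parameter
#' overrides for [oerParams()]), `oerParams` (alias), `tissues` (named
#' list of `{alphaX, betaX}`), `optimizer` (overrides for
#' [optimizerConfig()]), `beam` (field descriptions and [beamConfig()]
#' overrides), `phantom` (overrides for [phantomSpec()]), `synthetic`
#' (arguments of [syntheticCaseSpec()]), `prescription` and `seed`.
#'
#' @param path JSON file path.
#' @return the configuration as a list with class `"rowdRunConfig"`.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("validation error: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "rowdRunConfig")
}

## Internal: manifest written next to every command's outputs.
.writeManifest <- function(outDir, command, config, paths, seed) {
  manifest <- list(schema = MANIFEST_SCHEMA,
                   command = command,
                   package = "rowdplan",
                   version = as.character(utils::packageVersion("rowdplan")),
                   plan_schema = PLAN_SCHEMA,
                   seed = seed,
                   config = unclass(config),
                   outputs = as.list(paths),
                   checksums = as.list(tools::md5sum(paths)))
  mPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  mPath
}

#' Write a cumulative histogram to CSV
#'
#' @param h a [CumulativeHistogram-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeHistogram <- function(h, path) {
  utils::write.csv(data.frame(edge = h@edges, volume_fraction = h@volume),
                   path, row.names = FALSE)
  invisible(path)
}
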