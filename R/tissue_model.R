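#' Construct a tissue model
#'
#' A tissue model couples a voxel label grid with a per-label conductivity
#' table. Voxel centers sit at `origin_mm + (i - 1/2) * voxel_size_mm` on
#' each axis (millimetres, right-handed axes: +x lateral, +y anterior,
#' +z dorsal).
#'
#' @param label_grid 3-D integer array of voxel labels.
#' @param voxel_size_mm isotropic voxel edge length, millimetres.
#' @param origin_mm position of the grid corner (3-vector, mm).
#' @param conductivity_table data frame with columns `label`, `name`,
#'   `sigma_S_per_m` and optionally `eps_r`.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(label_grid, voxel_size_mm,
                         origin_mm = c(0, 0, 0),
                         conductivity_table = default_conductivity_table()) {
  if (length(dim(label_grid)) != 3L)
    stop("label_grid must be a 3-D array")
  if (any(dim(label_grid) < 2L))
    stop("grid must have at least 2 voxels per axis")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be > 0")
  storage.mode(label_grid) <- "integer"
  m <- structure(
    list(label_grid = label_grid,
         voxel_size_mm = voxel_size_mm,
         origin_mm = as.numeric(origin_mm),
         conductivity_table = conductivity_table),
    class = "tissue_model")
  validate_tissue_model(m)
  m
}

validate_tissue_model <- function(m) {
  used <- sort(unique(as.vector(m$label_grid)))
  used <- used[used != 0L]
  tab <- m$conductivity_table
  missing <- setdiff(used, tab$label)
  if (length(missing))
    stop("labels present in grid but missing from conductivity table: ",
         paste(missing, collapse = ", "))
  # tissue labels must conduct; electrode labels (insulation) may be 0
  tiss <- intersect(used, .tissue_labels())
  sig <- tab$sigma_S_per_m[match(tiss, tab$label)]
  if (any(sig <= 0))
    stop("tissue labels with non-positive conductivity: ",
         paste(tiss[sig <= 0], collapse = ", "))
  invisible(m)
}

#' @export
print.tissue_model <- function(x, ...) {
  dm <- dim(x$label_grid)
  cat(sprintf("tissue model: %d x %d x %d voxels @ %.3g mm (%.3g x %.3g x %.3g mm)\n",
              dm[1], dm[2], dm[3], x$voxel_size_mm,
              dm[1] * x$voxel_size_mm, dm[2] * x$voxel_size_mm,
              dm[3] * x$voxel_size_mm))
  tb <- table(x$label_grid)
  lab <- as.integer(names(tb))
  nm <- x$conductivity_table$name[match(lab, x$conductivity_table$label)]
  nm[is.na(nm)] <- "exterior"
  vol <- as.numeric(tb) * x$voxel_size_mm^3
  df <- data.frame(label = lab, name = nm, voxels = as.integer(tb),
                   volume_mm3 = round(vol, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

# per-voxel conductivity grid, S/m (0 for exterior/insulator/excluded)
sigma_grid <- function(model, exclude_labels = integer()) {
  tab <- model$conductivity_table
  maxl <- max(tab$label, 1L)
  lut <- numeric(maxl + 1L)
  lut[tab$label + 1L] <- tab$sigma_S_per_m
  if (length(exclude_labels)) lut[exclude_labels + 1L] <- 0
  arr <- lut[model$label_grid + 1L]
  dim(arr) <- dim(model$label_grid)
  arr
}

label_volumes <- function(model) {
  tb <- table(factor(model$label_grid))
  v <- as.numeric(tb) * model$voxel_size_mm^3
  names(v) <- names(tb)
  v
}

#' Replace heterogeneous tissue by a homogeneous conductor
#'
#' Maps every internal tissue label (including the encapsulation sheath and
#' the outer case shell) to a single conductivity, leaving electrode metal
#' and insulation entries untouched. Used to contrast heterogeneous against
#' homogeneous volume-conductor models at the conventional 0.3 S/m bulk
#' brain conductance.
#'
#' @param model a [tissue_model()].
#' @param sigma homogeneous conductivity, S/m; must be positive.
#' @return A tissue model with identical geometry and a flattened
#'   conductivity table.
#' @export
homogenize <- function(model, sigma = 0.3) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar")
  tab <- model$conductivity_table
  repl <- tab$label %in% .tissue_labels()
  tab$sigma_S_per_m[repl] <- sigma
  model$conductivity_table <- tab
  model
}

#' Read / write a tissue model
#'
#' The label volume is stored as a single-channel integer NIfTI and the
#' conductivity table as a TSV with columns `label`, `name`,
#' `sigma_S_per_m` and optionally `eps_r`; the grid origin is carried in a
#' `# origin_mm:` comment line of the TSV. `read_tissue_model(write...)`
#' round-trips labels, voxel size, origin and table values.
#'
#' @param label_volume_path path to the NIfTI label volume (.nii/.nii.gz).
#' @param conductivity_table_path path to the TSV conductivity table.
#' @return `read_tissue_model` returns a [tissue_model()];
#'   `write_tissue_model` returns the two paths invisibly.
#' @export
read_tissue_model <- function(label_volume_path, conductivity_table_path) {
  img <- RNifti::readNifti(label_volume_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("label volume must be a single-channel 3-D image")
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("label volume is not integer-valued")
  h <- RNifti::pixdim(img)[1]
  hdr <- readLines(conductivity_table_path, n = 5L)
  origin <- c(0, 0, 0)
  oline <- grep("^#\\s*origin_mm:", hdr, value = TRUE)
  if (length(oline))
    origin <- as.numeric(strsplit(sub("^#\\s*origin_mm:\\s*", "", oline[1]),
                                  "[ ,]+")[[1]])
  tab <- read.table(conductivity_table_path, header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "name", "sigma_S_per_m")
  if (!all(need %in% names(tab)))
    stop("conductivity table must have columns ",
         paste(need, collapse = ", "))
  arr <- round(arr)
  storage.mode(arr) <- "integer"
  tissue_model(arr, voxel_size_mm = h, origin_mm = origin,
               conductivity_table = tab)
}

#' @rdname read_tissue_model
#' @param model a [tissue_model()] to write.
#' @export
write_tissue_model <- function(model, label_volume_path,
                               conductivity_table_path) {
  arr <- model$label_grid
  attr(arr, "pixdim") <- rep(model$voxel_size_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"),
                     label_volume_path)
  con <- file(conductivity_table_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin_mm: %.9g %.9g %.9g", model$origin_mm[1],
                     model$origin_mm[2], model$origin_mm[3]), con)
  write.table(model$conductivity_table, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(label_volume_path, conductivity_table_path))
}
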