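#' @title Volume I/O and CT preprocessing
#' @name imaging_io
#' @description
#' Reading and writing volumes as NIfTI, plus the preprocessing applied
#' before modelling: in-plane downsampling to a fixed slice size at 1 pixel =
#' 1.4 mm, soft-tissue intensity windowing, Z-axis alignment of the three
#' contrast phases by nearest slice coordinate, and stacking into
#' three-channel dynamic images. Arrays are `(slice, row, col)`; channels are
#' the trailing dimension.
NULL

#' Load a single-phase volume
#'
#' Reads a NIfTI volume and returns intensities together with voxel spacing
#' and per-slice Z coordinates. The array convention is `(slice, row, col)`,
#' matching how the package writes volumes. DICOM series are not supported by
#' this build; convert to NIfTI first.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param format `"nifti"` (the supported format) or `"dicom"`.
#' @return list with `data`, `spacing_mm` `(z, y, x)`, `z_coords`, `path`.
#' @export
load_volume <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom")
    stop2("DICOM series reading is not supported by this build; convert the series to NIfTI")
  if (!file.exists(path)) stop2("cannot read volume: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop2("expected a 3D volume, got %d dims", length(d))
  sp <- abs(RNifti::pixdim(img))[1:3]
  data <- array(as.numeric(img), d)
  list(data = data, spacing_mm = sp,
       z_coords = (seq_len(d[1]) - 1) * sp[1], path = path)
}

#' Write a volume as NIfTI
#'
#' @param data 3D array `(slice, row, col)`.
#' @param path output `.nii` or `.nii.gz` path.
#' @param spacing_mm voxel spacing `(z, y, x)`.
#' @export
write_volume <- function(data, path, spacing_mm = c(2.5, 1.4, 1.4)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# error when per-slice Z coordinates have an irregular gap
check_slice_spacing <- function(z_coords, tol_frac = 0.5) {
  dz <- diff(z_coords)
  if (length(dz) == 0) return(invisible(TRUE))
  if (any(dz <= 0)) stop2("slice Z coordinates are not strictly increasing")
  md <- stats::median(dz)
  bad <- which(abs(dz - md) > tol_frac * md)
  if (length(bad))
    stop2("inconsistent slice spacing: Z gap of %.2f mm between z=%.2f and z=%.2f (expected %.2f mm)",
          dz[bad[1]], z_coords[bad[1]], z_coords[bad[1] + 1], md)
  invisible(TRUE)
}

#' Preprocess a CT volume to the modelling grid
#'
#' Resamples every slice in-plane so that 1 pixel = `target_spacing_mm`
#' (1.4 mm by default), then center-crops or pads to
#' `target_size x target_size`, clips intensities to the soft-tissue window
#' and min-max normalizes the volume to `[0, 1]`. Label volumes should use
#' `interpolation = "nearest"` with `clip = NULL, normalize = FALSE`.
#'
#' @param data 3D array `(slice, row, col)`.
#' @param spacing_mm input voxel spacing `(z, y, x)`; in-plane spacing must be
#'   isotropic to within 1%.
#' @param target_size output in-plane size (default 256).
#' @param target_spacing_mm output in-plane spacing (default 1.4).
#' @param clip HU window `c(lo, hi)` applied before normalization; `NULL`
#'   disables (default `c(-200, 300)`).
#' @param normalize min-max normalize to `[0, 1]` after clipping.
#' @param interpolation `"bilinear"` for intensities, `"nearest"` for labels.
#' @return list with `data` (`slices x target_size x target_size`),
#'   `spacing_mm`.
#' @export
preprocess <- function(data, spacing_mm, target_size = 256,
                       target_spacing_mm = 1.4, clip = c(-200, 300),
                       normalize = TRUE,
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(data)
  sy <- spacing_mm[2]; sx <- spacing_mm[3]
  if (abs(sy - sx) / sx > 0.01)
    stop2("anisotropic in-plane spacing (%.3f vs %.3f mm) beyond tolerance", sy, sx)
  new_h <- max(1L, as.integer(round(d[2] * sy / target_spacing_mm)))
  new_w <- max(1L, as.integer(round(d[3] * sx / target_spacing_mm)))
  filt <- if (interpolation == "bilinear") "bilinear" else "none"
  pad_val <- if (!is.null(clip)) clip[1] else 0
  out <- array(pad_val, c(d[1], target_size, target_size))
  for (s in seq_len(d[1])) {
    sl <- data[s, , ]
    if (new_h != d[2] || new_w != d[3])
      sl <- as.matrix(EBImage::resize(sl, w = new_h, h = new_w, filter = filt))
    # center crop / pad to target_size
    src_r <- .center_range(new_h, target_size)
    src_c <- .center_range(new_w, target_size)
    out[s, src_r$dst, src_c$dst] <- sl[src_r$src, src_c$src]
  }
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  if (normalize) {
    rng <- range(out)
    out <- if (diff(rng) > 0) (out - rng[1]) / diff(rng) else out * 0
  }
  list(data = out, spacing_mm = c(spacing_mm[1], target_spacing_mm,
                                  target_spacing_mm))
}

.center_range <- function(n_src, n_dst) {
  if (n_src >= n_dst) {
    off <- (n_src - n_dst) %/% 2
    list(src = seq_len(n_dst) + off, dst = seq_len(n_dst))
  } else {
    off <- (n_dst - n_src) %/% 2
    list(src = seq_len(n_src), dst = seq_len(n_src) + off)
  }
}

#' Align the three contrast phases along Z
#'
#' Matches non-contrast, arterial and portal-venous volumes to the common Z
#' range by nearest slice coordinate (tolerance: half the median slice gap of
#' the portal-venous phase, which supplies the reference grid). Slices
#' without a counterpart in every phase are dropped; an empty Z overlap is an
#' error, mirroring the exclusion of cases that cannot be aligned.
#'
#' @param nc,art,pv lists as returned by [load_volume()] (fields `data`,
#'   `z_coords`, `spacing_mm`).
#' @param case_id identifier stored on the result.
#' @return a `dynamic_ct_volume`: list with `phases`
#'   (`$non_contrast/$arterial/$portal_venous`), `spacing_mm`, `z_coords`,
#'   `case_id`.
#' @export
align_phases <- function(nc, art, pv, case_id = "case") {
  for (p in list(nc, art, pv)) check_slice_spacing(p$z_coords)
  zmin <- max(min(nc$z_coords), min(art$z_coords), min(pv$z_coords))
  zmax <- min(max(nc$z_coords), max(art$z_coords), max(pv$z_coords))
  if (zmin > zmax)
    stop2("phases have no overlapping Z range (cannot align along Z)")
  ref_z <- pv$z_coords[pv$z_coords >= zmin - 1e-9 & pv$z_coords <= zmax + 1e-9]
  tol <- stats::median(diff(pv$z_coords)) / 2
  pick <- function(phase) {
    idx <- vapply(ref_z, function(z) {
      j <- which.min(abs(phase$z_coords - z))
      if (abs(phase$z_coords[j] - z) > tol + 1e-9)
        stop2("no %s slice within %.2f mm of z=%.2f", "phase", tol, z)
      j
    }, integer(1))
    phase$data[idx, , , drop = FALSE]
  }
  structure(list(
    phases = list(non_contrast = pick(nc), arterial = pick(art),
                  portal_venous = pick(pv)),
    spacing_mm = pv$spacing_mm, z_coords = ref_z, case_id = case_id),
    class = "dynamic_ct_volume")
}

#' Stack phases of one slice into a multi-channel image
#'
#' Channel order is fixed as (non-contrast, arterial, portal-venous) for the
#' dynamic stack; a subset of phases yields fewer channels (e.g. the
#' portal-venous-only input of the liver and large-tumor models).
#'
#' @param volume a `dynamic_ct_volume` or a `phantom_case$volume` list.
#' @param slice_index 1-based slice index.
#' @param phases which phases, in stack order.
#' @return `(H, W, n_phases)` array.
#' @export
stack_dynamic <- function(volume, slice_index,
                          phases = c("non_contrast", "arterial",
                                     "portal_venous")) {
  ph <- volume$phases
  ns <- dim(ph[[1]])[1]
  if (slice_index < 1 || slice_index > ns)
    stop2("slice index %d out of range 1..%d", slice_index, ns)
  bad <- setdiff(phases, names(ph))
  if (length(bad)) stop2("unknown phase(s): %s", paste(bad, collapse = ", "))
  h <- dim(ph[[1]])[2]; w <- dim(ph[[1]])[3]
  out <- array(0, c(h, w, length(phases)))
  for (k in seq_along(phases)) out[, , k] <- ph[[phases[k]]][slice_index, , ]
  out
}

#' Write a phantom case to disk
#'
#' Per-phase volumes, liver mask and tumor instance labels as NIfTI
#' (`.nii.gz`), the tumor manifest as CSV, and a JSON sidecar with case id
#' and spacing.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$volume$spacing_mm
  for (p in names(case$volume$phases))
    write_volume(case$volume$phases[[p]], file.path(dir, paste0(p, ".nii.gz")), sp)
  write_volume(case$liver_mask + 0, file.path(dir, "liver_mask.nii.gz"), sp)
  write_volume(case$tumor_labels, file.path(dir, "tumor_labels.nii.gz"), sp)
  utils::write.csv(case$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(case_id = case$volume$case_id, spacing_mm = sp),
                       file.path(dir, "case.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a phantom case written by [write_phantom_case()]
#'
#' @param dir case directory.
#' @return a `phantom_case`-like list (without the generating spec).
#' @export
read_phantom_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"), simplifyVector = TRUE)
  phases <- lapply(c(non_contrast = "non_contrast", arterial = "arterial",
                     portal_venous = "portal_venous"),
                   function(p) load_volume(file.path(dir, paste0(p, ".nii.gz")))$data)
  liver <- load_volume(file.path(dir, "liver_mask.nii.gz"))$data > 0.5
  labels <- array(as.integer(round(
    load_volume(file.path(dir, "tumor_labels.nii.gz"))$data)),
    dim(liver))
  sp <- as.numeric(meta$spacing_mm)
  structure(list(
    volume = list(phases = phases, spacing_mm = sp,
                  z_coords = (seq_len(dim(liver)[1]) - 1) * sp[1],
                  case_id = meta$case_id),
    liver_mask = liver, tumor_labels = labels,
    manifest = utils::read.csv(file.path(dir, "manifest.csv"))),
    class = "phantom_case")
}
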