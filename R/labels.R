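#' Voxel label conventions
#'
#' Fixed integer labels shared by every module. Label 0 is reserved for
#' exterior/air and never conducts. Labels 1-9 are tissues, 10-11 the
#' peri-electrode materials, and 21-28 the eight lead contacts in
#' tip-to-shaft order (1, 2A, 2B, 2C, 3A, 3B, 3C, 4).
#'
#' @format A named integer vector.
#' @export
pallidal_labels <- c(
  exterior = 0L,
  grey_matter = 1L,
  white_matter = 2L,
  csf = 3L,
  gpe = 4L,
  lamina = 5L,
  gpi = 6L,
  internal_capsule = 7L,
  optic_tract = 8L,
  case = 9L,
  encapsulation = 10L,
  insulation = 11L,
  contact_1 = 21L,
  contact_2A = 22L,
  contact_2B = 23L,
  contact_2C = 24L,
  contact_3A = 25L,
  contact_3B = 26L,
  contact_3C = 27L,
  contact_4 = 28L
)

.contact_ids <- c("1", "2A", "2B", "2C", "3A", "3B", "3C", "4")

contact_label <- function(id) {
  idx <- match(id, .contact_ids)
  if (anyNA(idx)) stop("unknown contact id(s): ",
                       paste(id[is.na(idx)], collapse = ", "))
  pallidal_labels[paste0("contact_", .contact_ids[idx])]
}

#' Default label-to-conductivity table
#'
#' Electrical conductivities (S/m) for the phantom tissues at low frequency.
#' Grey matter 0.275, white matter 0.126 and CSF 1.654 follow widely used
#' low-frequency tissue-property compilations; both pallidal segments are
#' treated as grey matter and the medial medullary lamina, internal capsule
#' and optic tract as white matter. The fibrous encapsulation sheath gets
#' 0.1 S/m, the outer case/epidermis shell 0.17 S/m. Polyurethane insulation
#' has conductivity 0 and is excluded from the conductance grid; the
#' platinum-iridium value for the contacts is nominal (active contacts are
#' potential-clamped and inactive ones excluded during a solve).
#'
#' @return A data frame with columns `label`, `name`, `sigma_S_per_m`,
#'   `eps_r`.
#' @export
default_conductivity_table <- function() {
  data.frame(
    label = unname(pallidal_labels),
    name = names(pallidal_labels),
    sigma_S_per_m = c(
      0,        # exterior
      0.275,    # grey matter
      0.126,    # white matter
      1.654,    # CSF
      0.275,    # GPe
      0.126,    # lamina (treated as white matter)
      0.275,    # GPi
      0.126,    # internal capsule
      0.126,    # optic tract
      0.17,     # case / epidermis shell
      0.1,      # encapsulation
      0,        # polyurethane insulation
      rep(9.43e6, 8)  # platinum-iridium contacts
    ),
    eps_r = c(0, 1e5, 7e4, 109, 1e5, 7e4, 1e5, 7e4, 7e4, 1e3, 1e4, 3.5,
              rep(1, 8)),
    stringsAsFactors = FALSE
  )
}

# label groups used by homogenize() and the VTA partition
.tissue_labels <- function() c(1L:9L, 10L)        # replaced by homogenize()
.electrode_labels <- function() c(11L, 21L:28L)   # untouched by homogenize()
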