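#' Lead specification
#'
#' Geometric description of a DBS lead: number of contact levels, contact
#' length, centre-to-centre pitch, and the distance from the physical lead
#' tip to the centre of the most distal contact.  Directional leads are
#' modelled as rings at each contact level (segment azimuths are ignored;
#' all positional accuracy metrics in this package are ring-centre based).
#'
#' @param model_name manufacturer model identifier, e.g. `"3389"`.
#' @param n_contacts number of contact levels (>= 1).
#' @param contact_length contact length along the lead axis, mm.
#' @param contact_pitch centre-to-centre spacing of consecutive contacts,
#'   mm; must be >= `contact_length`.
#' @param tip_to_first_contact_centre distance from the lead tip to the
#'   centre of contact 0 (the most distal contact), mm.
#' @param directional logical; `TRUE` for segmented leads.
#' @return an object of class `lead_spec`.
#' @export
lead_spec <- function(model_name, n_contacts, contact_length, contact_pitch,
                      tip_to_first_contact_centre, directional = FALSE) {
  n_contacts <- as.integer(n_contacts)
  if (is.na(n_contacts) || n_contacts < 1L)
    stop("'n_contacts' must be a count >= 1")
  if (!is.numeric(contact_length) || contact_length <= 0)
    stop("'contact_length' must be > 0")
  if (!is.numeric(contact_pitch) || contact_pitch < contact_length)
    stop("'contact_pitch' must be >= 'contact_length'")
  if (!is.numeric(tip_to_first_contact_centre) ||
      tip_to_first_contact_centre < 0)
    stop("'tip_to_first_contact_centre' must be >= 0")
  structure(list(model_name = as.character(model_name),
                 n_contacts = n_contacts,
                 contact_length = as.numeric(contact_length),
                 contact_pitch = as.numeric(contact_pitch),
                 tip_to_first_contact_centre =
                   as.numeric(tip_to_first_contact_centre),
                 directional = isTRUE(directional)),
            class = "lead_spec")
}

#' Electrode model
#'
#' An implanted electrode: the world-space tip position, the unit direction
#' pointing from the tip towards the entry point (i.e. up the lead shaft),
#' the lead geometry, and the hemisphere.  The left hemisphere is always
#' implantation order 1 and the right order 2, reflecting a left-first
#' surgical routine; the order is derived, not free.
#'
#' @param tip length-3 world coordinate of the lead tip, mm.
#' @param direction length-3 vector from tip towards entry; it is
#'   normalised by the constructor and must be non-zero.
#' @param spec a [lead_spec].
#' @param hemisphere `"left"` or `"right"`.
#' @return an object of class `electrode_model`.
#' @export
electrode_model <- function(tip, direction, spec,
                            hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  tip <- as.numeric(tip)
  direction <- as.numeric(direction)
  if (length(tip) != 3L || length(direction) != 3L)
    stop("'tip' and 'direction' must be length-3 numeric vectors")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("'direction' must be non-zero")
  if (!inherits(spec, "lead_spec")) stop("'spec' must be a lead_spec")
  structure(list(tip = tip,
                 direction = direction / nrm,
                 spec = spec,
                 hemisphere = hemisphere,
                 implantation_order = if (hemisphere == "left") 1L else 2L),
            class = "electrode_model")
}

#' @export
print.electrode_model <- function(x, ...) {
  cat(sprintf("<electrode_model> %s lead, %s hemisphere (order %d)\n",
              x$spec$model_name, x$hemisphere, x$implantation_order))
  cat(sprintf("  tip (%.2f, %.2f, %.2f) mm, direction (%.3f, %.3f, %.3f)\n",
              x$tip[1], x$tip[2], x$tip[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Contact-centre coordinates of an electrode
#'
#' Contact `k` (0-based, distal to proximal) lies at
#' `tip + direction * (tip_to_first_contact_centre + k * pitch)`.
#'
#' @param electrode an [electrode_model].
#' @return `n_contacts` x 3 matrix of world coordinates (mm), ordered
#'   distal to proximal.
#' @export
contact_centers <- function(electrode) {
  if (!inherits(electrode, "electrode_model"))
    stop("'electrode' must be an electrode_model")
  nrm <- sqrt(sum(electrode$direction^2))
  if (abs(nrm - 1) > 1e-9)
    stop("electrode direction is not a unit vector (norm ", format(nrm), ")")
  sp <- electrode$spec
  k <- seq_len(sp$n_contacts) - 1
  offs <- sp$tip_to_first_contact_centre + k * sp$contact_pitch
  t(electrode$tip + outer(electrode$direction, offs))
}

lead_spec_fields <- c("n_contacts", "contact_length", "contact_pitch",
                      "tip_to_first_contact_centre")

#' Load a lead geometry library
#'
#' Reads a JSON file holding an array of lead specifications and returns a
#' named list of [lead_spec] objects keyed by model name.  Fields other
#' than the geometric ones (e.g. free-text provenance notes) are ignored.
#' The library shipped with the package
#' (`system.file("extdata", "lead_library.json", package = "dbsaudit")`)
#' covers the common Medtronic, Abbott/St Jude and Boston Scientific
#' models; its values are nominal datasheet geometry and are editable.
#'
#' @param path path to a JSON lead library; defaults to the shipped file.
#' @return named list of [lead_spec], possibly empty.
#' @export
load_lead_library <- function(path = system.file("extdata",
                                                 "lead_library.json",
                                                 package = "dbsaudit")) {
  if (!file.exists(path)) stop("lead library not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0L) return(structure(list(), names = character()))
  out <- list()
  for (entry in raw) {
    nm <- entry$model_name
    if (is.null(nm)) stop("lead library entry without 'model_name'")
    if (nm %in% names(out)) stop("duplicate model name '", nm, "'")
    for (f in lead_spec_fields) {
      v <- entry[[f]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v))
        stop("malformed numeric field '", f, "' for model '", nm, "'")
    }
    out[[nm]] <- lead_spec(nm, entry$n_contacts, entry$contact_length,
                           entry$contact_pitch,
                           entry$tip_to_first_contact_centre,
                           isTRUE(entry$directional))
  }
  out
}

#' Write a lead geometry library
#'
#' @param library named list of [lead_spec] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_lead_library <- function(library, path) {
  entries <- lapply(library, function(sp) unclass(sp))
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
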