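#' Functional brain network definitions
#'
#' The analysis operates on seven canonical resting-state networks; six ship
#' with region lists (sensorimotor, auditory, visual, frontoparietal,
#' salience, attention). The default-mode network has no packaged region list
#' and must be supplied by the user (e.g. through the YAML file) before it can
#' be analyzed.
#'
#' @return a named list of `network_definition` objects (`name`, `regions`).
#' @export
default_networks <- function() {
  defs <- list(
    sensorimotor = c("Left Precentral Gyrus", "Left Postcentral Gyrus",
                     "Paracentral Lobule", "Right Precentral Gyrus",
                     "Right Postcentral Gyrus"),
    auditory = c("Left Supramarginal Gyrus", "Left Superior Temporal Gyrus",
                 "Right Supramarginal Gyrus", "Right Superior Temporal Gyrus",
                 "Transverse Temporal Gyrus"),
    visual = c("Pericalcarine Gyrus", "Lingual Gyrus", "Lateral Occipital Gyrus",
               "Fusiform Gyrus", "Cuneus Gyrus"),
    frontoparietal = c("Left Superior Frontal Gyrus", "Right Superior Frontal Gyrus",
                       "Rostral Middle Frontal Gyrus", "Caudal Middle Frontal Gyrus",
                       "Pars Triangularis Gyrus", "Medial Orbitofrontal Gyrus",
                       "Inferior Parietal Gyrus"),
    salience = c("Caudal Anterior Cingulate Gyrus", "Caudal Middle Frontal Gyrus",
                 "Insula Gyrus", "Pars Triangularis Gyrus",
                 "Rostral Anterior Cingulate Gyrus", "Rostral Middle Frontal Gyrus",
                 "Superior Parietal Gyrus"),
    attention = c("Right Superior Temporal Gyrus", "Left Superior Temporal Gyrus",
                  "Superior Parietal Gyrus", "Pars Triangularis Gyrus",
                  "Inferior Parietal Gyrus", "Rostral Middle Frontal Gyrus",
                  "Caudal Middle Frontal Gyrus")
  )
  mapply(network_definition, names(defs), defs, SIMPLIFY = FALSE)
}

#' Construct a network definition
#'
#' @param name network name.
#' @param regions ordered character vector of 2 to 12 unique ROI names.
#' @return an object of class `network_definition`.
#' @export
network_definition <- function(name, regions) {
  regions <- as.character(regions)
  if (anyDuplicated(regions)) stop("network regions must be unique", call. = FALSE)
  if (length(regions) < 2 || length(regions) > 12) {
    stop("a network must have between 2 and 12 regions (exact enumeration bound)",
         call. = FALSE)
  }
  structure(list(name = name, regions = regions), class = "network_definition")
}

#' @export
print.network_definition <- function(x, ...) {
  cat(sprintf("Network '%s' (%d regions): %s\n", x$name, length(x$regions),
              paste(x$regions, collapse = ", ")))
  invisible(x)
}

#' Load network definitions from a YAML file
#'
#' The YAML maps network names to region lists; the packaged file
#' (`system.file("extdata", "networks.yaml", package = "tmslandscape")`)
#' carries the shipped defaults and can be edited, e.g. to add a default-mode
#' entry.
#'
#' @param path YAML file path; defaults to the packaged file.
#' @return named list of `network_definition` objects.
#' @export
load_networks <- function(path = system.file("extdata", "networks.yaml",
                                             package = "tmslandscape")) {
  raw <- yaml::read_yaml(path)
  mapply(network_definition, names(raw), raw, SIMPLIFY = FALSE)
}

#' All distinct ROIs referenced by a set of networks
#'
#' @param networks list of `network_definition`s.
#' @return character vector of unique region names in order of first use.
#' @export
all_rois <- function(networks) {
  unique(unlist(lapply(networks, `[[`, "regions"), use.names = FALSE))
}

# driving network of each ROI in the generator: first network containing it
roi_owner <- function(networks) {
  rois <- all_rois(networks)
  owner <- vapply(rois, function(r) {
    names(networks)[which(vapply(networks, function(nw) r %in% nw$regions, logical(1)))[1L]]
  }, character(1))
  owner
}
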