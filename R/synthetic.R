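.DEFAULT_TYPES <- c("Tumor", "Epithelium", "Fibroblast", "Endothelium",
                    "Macrophage_M1", "Macrophage_M2", "Neutrophil", "NK",
                    "B_cell", "CD4_T", "CD8_T", "Treg", "DC", "CD103_DC")

.DEFAULT_MARKERS <- c("PD1", "PDL1", "CD86", "CXCL9", "Ki67", "cCasp3",
                      "LAG3")

.defaultComposition <- function() {
  types <- .DEFAULT_TYPES
  comp <- matrix(0, 3, length(types),
                 dimnames = list(c("normal", "interface", "tumor"), types))
  # each region is anchored by types rare elsewhere (normal: epithelium;
  # interface: myeloid band; tumor core: tumor cells), and diffuse T/DC
  # content outside hubs is low: T cells and DCs concentrate in the
  # planted aggregates, mirroring tumor tissue where most T cells sit in
  # a handful of communities
  comp["normal", c("Epithelium", "Fibroblast", "Endothelium", "B_cell",
                   "CD4_T", "CD8_T", "Macrophage_M1", "NK")] <-
    c(0.62, 0.16, 0.10, 0.04, 0.03, 0.02, 0.02, 0.01)
  comp["interface", c("Tumor", "Macrophage_M1", "Macrophage_M2",
                      "Neutrophil", "NK", "Fibroblast", "Endothelium",
                      "B_cell", "CD4_T", "CD8_T", "Treg", "DC")] <-
    c(0.12, 0.22, 0.14, 0.12, 0.07, 0.14, 0.09, 0.04, 0.02, 0.02, 0.01,
      0.01)
  comp["tumor", c("Tumor", "Macrophage_M2", "Endothelium",
                  "Neutrophil")] <- c(0.88, 0.06, 0.03, 0.03)
  comp
}

.defaultMarkerMeans <- function() {
  m <- matrix(log(0.1), length(.DEFAULT_MARKERS), length(.DEFAULT_TYPES),
              dimnames = list(.DEFAULT_MARKERS, .DEFAULT_TYPES))
  m["PD1", c("CD8_T", "CD4_T", "Treg")] <- -0.7
  m["PDL1", "Tumor"] <- -0.7
  m["PDL1", "DC"] <- -1.0
  m["CD86", c("DC", "CD103_DC", "Macrophage_M1")] <- -0.7
  m["CXCL9", c("DC", "CD103_DC", "Macrophage_M1")] <- -1.2
  m["Ki67", "Tumor"] <- -0.3
  m["cCasp3", ] <- -2.5
  m["cCasp3", "Tumor"] <- -2.0
  m["LAG3", "CD8_T"] <- -1.5
  m
}

.defaultMarkerShifts <- function() {
  # activation phenotype of the interface T/DC hubs: CXCL9-high DCs,
  # PD-1-high T cells, proliferating T cells
  data.frame(
    marker = c("CXCL9", "CXCL9", "PD1", "PD1", "PD1", "Ki67", "Ki67"),
    cell_type = c("DC", "CD103_DC", "CD8_T", "CD4_T", "Treg", "CD8_T",
                  "CD4_T"),
    community = "T_DC_hub",
    group = NA_character_,
    dmu = c(1.2, 1.2, 0.8, 0.8, 0.8, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

#' Describe one kind of planted hub community
#'
#' @param name planted community id.
#' @param n_instances hub instances per image; default 3.
#' @param radius hub radius in um; default 30.
#' @param n_cells cells per instance; default 70.
#' @param composition named cell-type probability vector (sums to 1).
#' @param placement \code{"interface"} (default) or \code{"normal"}.
#' @param conditioning_type optional cell type present in only a fraction
#'   of instances (e.g. "Treg"); see \linkS4class{HubSpec}.
#' @param conditioning_prob fraction of instances containing the
#'   conditioning type (rounded to a fixed count per image); default 0.5.
#' @param segregate_types cell types displaced away from the hub core in
#'   conditioned instances (suppressing their adjacency to the rest).
#' @param segregate_offset displacement in um; default 45.
#' @return A \linkS4class{HubSpec}.
#' @export
hubSpec <- function(name, n_instances = 3, radius = 30, n_cells = 70,
                    composition, placement = "interface",
                    conditioning_type = character(0),
                    conditioning_prob = 0.5,
                    segregate_types = character(0),
                    segregate_offset = 45) {
  methods::new("HubSpec", name = name, n_instances = as.integer(n_instances),
               radius = as.numeric(radius), n_cells = as.integer(n_cells),
               composition = composition, placement = placement,
               conditioning_type = conditioning_type,
               conditioning_prob = as.numeric(conditioning_prob),
               segregate_types = segregate_types,
               segregate_offset = as.numeric(segregate_offset))
}

.defaultHubs <- function() {
  list(
    hubSpec("T_DC_hub", n_instances = 3, radius = 30, n_cells = 70,
            composition = c(DC = 0.18, CD103_DC = 0.07, CD4_T = 0.30,
                            CD8_T = 0.30, Treg = 0.15)),
    hubSpec("B_follicle", n_instances = 2, radius = 25, n_cells = 50,
            composition = c(B_cell = 0.75, CD4_T = 0.15, DC = 0.10),
            placement = "normal"))
}

#' Create a synthetic tissue specification
#'
#' Default geometry is a 0.8 x 0.8 mm field with a 240 um circular tumor
#' core, a 70 um interface annulus, near-confluent IMC-scale cell densities
#' (6000-10000 cells/mm^2 depending on region, giving 15-um neighborhoods
#' of about 4-8 cells), 14 cell types at region-specific
#' mixtures, three planted T/DC interface hubs plus two B-cell follicles,
#' and seven markers drawn log-normally with hub-dependent activation
#' shifts. All arguments override the defaults; see \linkS4class{TissueSpec}
#' for slot semantics.
#'
#' @param field_width,field_height field size in um.
#' @param tumor_center numeric (x, y).
#' @param tumor_radius,interface_width geometry in um.
#' @param densities named vector (normal, interface, tumor) in cells/um^2.
#' @param composition 3 x T region composition matrix.
#' @param hubs list of \linkS4class{HubSpec}.
#' @param marker_means markers x types meanlog matrix.
#' @param marker_sdlog log-normal sdlog; default 0.7.
#' @param marker_shifts data.frame (marker, cell_type, community, group,
#'   dmu), NA = wildcard.
#' @param group arm label; default "vehicle".
#' @param seed random seed.
#' @return A \linkS4class{TissueSpec}.
#' @export
tissueSpec <- function(field_width = 800, field_height = 800,
                       tumor_center = c(400, 400), tumor_radius = 240,
                       interface_width = 70,
                       densities = c(normal = 0.006, interface = 0.008,
                                     tumor = 0.010),
                       composition = .defaultComposition(),
                       hubs = .defaultHubs(),
                       marker_means = .defaultMarkerMeans(),
                       marker_sdlog = 0.7,
                       marker_shifts = .defaultMarkerShifts(),
                       group = "vehicle", seed = 1L) {
  methods::new("TissueSpec", field_width = as.numeric(field_width),
               field_height = as.numeric(field_height),
               tumor_center = as.numeric(tumor_center),
               tumor_radius = as.numeric(tumor_radius),
               interface_width = as.numeric(interface_width),
               densities = densities, composition = composition,
               hubs = hubs, marker_means = marker_means,
               marker_sdlog = as.numeric(marker_sdlog),
               marker_shifts = marker_shifts, group = group,
               seed = as.integer(seed))
}

setMethod("show", "TissueSpec", function(object) {
  cat("TissueSpec:", object@field_width, "x", object@field_height,
      "um field; tumor r =", object@tumor_radius, "+",
      object@interface_width, "um interface;",
      ncol(object@composition), "cell types;", length(object@hubs),
      "hub spec(s); group", object@group, "; seed", object@seed, "\n")
})

.sampleDisk <- function(n, center, r_min, r_max) {
  r <- sqrt(stats::runif(n, r_min^2, r_max^2))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(a), center[2] + r * sin(a))
}

.sampleTruncGauss <- function(n, center, sd, radius) {
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  while (length(need) > 0) {
    cand <- cbind(stats::rnorm(length(need), center[1], sd),
                  stats::rnorm(length(need), center[2], sd))
    ok <- (cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2 <= radius^2
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

#' Generate one synthetic tissue image
#'
#' Background cells are placed by homogeneous Poisson processes in the
#' tumor core, interface annulus, and normal region, with cell types drawn
#' from the region compositions; hub instances are isotropic Gaussian blobs
#' (sd = radius/2, truncated at the hub radius) centered on the interface
#' annulus or in the normal region; marker intensities are log-normal with
#' (marker, cell type, community, group)-dependent meanlog. Fully
#' reproducible from \code{spec@seed}.
#'
#' @param spec a \linkS4class{TissueSpec}.
#' @param image_id ROI identifier; default "img1".
#' @return list with \code{cells} (a \linkS4class{CellTable}; the
#'   \code{domain} column carries the region) and \code{truth}
#'   (data.frame cell_id, region, community: planted hub name or region
#'   name), in matching order.
#' @export
generateTissue <- function(spec, image_id = "img1") {
  methods::validObject(spec)
  types <- colnames(spec@composition)
  withr::with_seed(spec@seed, {
    r0 <- spec@tumor_radius
    r1 <- r0 + spec@interface_width
    areas <- c(normal = spec@field_width * spec@field_height - pi * r1^2,
               interface = pi * (r1^2 - r0^2),
               tumor = pi * r0^2)
    xy <- NULL; ctype <- character(0); region <- character(0)
    community <- character(0)
    for (reg in c("normal", "interface", "tumor")) {
      n_reg <- stats::rpois(1, spec@densities[reg] * areas[reg])
      if (n_reg == 0) next
      pts <- switch(reg,
        tumor = .sampleDisk(n_reg, spec@tumor_center, 0, r0),
        interface = .sampleDisk(n_reg, spec@tumor_center, r0, r1),
        normal = {
          # rejection sampling of the field outside the interface annulus
          out <- matrix(NA_real_, n_reg, 2)
          need <- seq_len(n_reg)
          while (length(need) > 0) {
            cand <- cbind(stats::runif(length(need), 0, spec@field_width),
                          stats::runif(length(need), 0, spec@field_height))
            ok <- (cand[, 1] - spec@tumor_center[1])^2 +
              (cand[, 2] - spec@tumor_center[2])^2 > r1^2
            out[need[ok], ] <- cand[ok, , drop = FALSE]
            need <- need[!ok]
          }
          out
        })
      xy <- rbind(xy, pts)
      ctype <- c(ctype, sample(types, n_reg, replace = TRUE,
                               prob = spec@composition[reg, ]))
      region <- c(region, rep(reg, n_reg))
      community <- c(community, rep(reg, n_reg))
    }
    for (h in spec@hubs) {
      n_cond <- if (length(h@conditioning_type) == 0) 0L else
        as.integer(round(h@n_instances * h@conditioning_prob))
      cond_inst <- if (n_cond > 0)
        sample.int(h@n_instances, n_cond) else integer(0)
      for (inst in seq_len(h@n_instances)) {
        center <- if (h@placement == "interface") {
          a <- stats::runif(1, 0, 2 * pi)
          rc <- r0 + spec@interface_width / 2
          spec@tumor_center + rc * c(cos(a), sin(a))
        } else {
          repeat {
            cand <- c(stats::runif(1, h@radius,
                                   spec@field_width - h@radius),
                      stats::runif(1, h@radius,
                                   spec@field_height - h@radius))
            if (sum((cand - spec@tumor_center)^2) > (r1 + h@radius)^2)
              break
          }
          cand
        }
        comp <- h@composition
        conditioned <- inst %in% cond_inst
        if (length(h@conditioning_type) > 0 && !conditioned) {
          comp <- comp[setdiff(names(comp), h@conditioning_type)]
          comp <- comp / sum(comp)
        }
        htypes <- sample(names(comp), h@n_cells, replace = TRUE,
                         prob = comp)
        pts <- .sampleTruncGauss(h@n_cells, center, h@radius / 2, h@radius)
        if (conditioned && length(h@segregate_types) > 0) {
          seg <- htypes %in% h@segregate_types
          if (any(seg)) {
            a <- stats::runif(1, 0, 2 * pi)
            center2 <- center +
              (h@radius + h@segregate_offset) * c(cos(a), sin(a))
            pts[seg, ] <- .sampleTruncGauss(sum(seg), center2,
                                            h@radius / 2, h@radius)
          }
        }
        pts[, 1] <- pmin(pmax(pts[, 1], 0), spec@field_width)
        pts[, 2] <- pmin(pmax(pts[, 2], 0), spec@field_height)
        d2 <- (pts[, 1] - spec@tumor_center[1])^2 +
          (pts[, 2] - spec@tumor_center[2])^2
        hreg <- ifelse(d2 <= r0^2, "tumor",
                       ifelse(d2 <= r1^2, "interface", "normal"))
        xy <- rbind(xy, pts)
        ctype <- c(ctype, htypes)
        region <- c(region, hreg)
        community <- c(community, rep(h@name, h@n_cells))
      }
    }
    n <- nrow(xy)
    markers <- rownames(spec@marker_means)
    mu <- spec@marker_means[, ctype, drop = FALSE]
    sh <- spec@marker_shifts
    if (nrow(sh) > 0) for (i in seq_len(nrow(sh))) {
      hit <- (is.na(sh$cell_type[i]) | ctype == sh$cell_type[i]) &
        (is.na(sh$community[i]) | community == sh$community[i]) &
        (is.na(sh$group[i]) | spec@group == sh$group[i])
      mu[sh$marker[i], hit] <- mu[sh$marker[i], hit] + sh$dmu[i]
    }
    intens <- matrix(stats::rlnorm(length(markers) * n,
                                   meanlog = as.vector(mu),
                                   sdlog = spec@marker_sdlog),
                     nrow = length(markers),
                     dimnames = list(markers, NULL))
    df <- data.frame(cell_id = sprintf("c%06d", seq_len(n)),
                     image_id = image_id, x = xy[, 1], y = xy[, 2],
                     cell_type = ctype, domain = region,
                     group = spec@group, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(t(intens)))
    cells <- CellTable(df, palette = types)
    truth <- data.frame(cell_id = df$cell_id, region = region,
                        community = community, stringsAsFactors = FALSE)
  })
  list(cells = cells, truth = truth)
}

#' Generate a cohort of synthetic images
#'
#' Generates \code{n_images} independent tissues from one specification,
#' with per-image seeds derived from the master seed by a fixed counter
#' (\code{seed + image index}) so any image is independently reproducible.
#' \code{group_effects} applies arm-specific modifications before
#' generation; allowed keys: \code{marker_mu_shift} (data.frame rows
#' appended to the spec's marker shifts, e.g. a PD-1 meanlog increase on
#' hub CD8 cells in the treated arm), \code{hub_scale} (multiplies each
#' hub's instance count, rounded), \code{density_scale} (multiplies all
#' region densities). Unknown keys are an error.
#'
#' @param spec a \linkS4class{TissueSpec}.
#' @param n_images number of images (>= 1).
#' @param group optional arm label overriding \code{spec@group}.
#' @param group_effects named list of effects (see above).
#' @param image_prefix prefix of generated image ids.
#' @return list of per-image lists (\code{cells}, \code{truth}).
#' @export
generateCohort <- function(spec, n_images, group = NULL,
                           group_effects = list(),
                           image_prefix = "img") {
  if (n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  allowed <- c("marker_mu_shift", "hub_scale", "density_scale")
  unknown <- setdiff(names(group_effects), allowed)
  if (length(unknown) > 0)
    stop("unknown group effect key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(group)) spec@group <- group
  if (!is.null(group_effects$marker_mu_shift))
    spec@marker_shifts <- rbind(spec@marker_shifts,
                                group_effects$marker_mu_shift)
  if (!is.null(group_effects$hub_scale))
    spec@hubs <- lapply(spec@hubs, function(h) {
      h@n_instances <- as.integer(round(h@n_instances *
                                          group_effects$hub_scale))
      h
    })
  if (!is.null(group_effects$density_scale))
    spec@densities <- spec@densities * group_effects$density_scale
  spec@hubs <- Filter(function(h) h@n_instances > 0, spec@hubs)
  lapply(seq_len(n_images), function(i) {
    spec_i <- spec
    spec_i@seed <- spec@seed + i
    generateTissue(spec_i, image_id = sprintf("%s%02d", image_prefix, i))
  })
}

#' Combine per-image cell tables into one
#'
#' @param tables list of \linkS4class{CellTable} objects sharing a palette.
#' @return a single \linkS4class{CellTable}.
#' @export
combineCellTables <- function(tables) {
  df <- do.call(rbind, lapply(tables, as.data.frame))
  CellTable(df, palette = cellTypePalette(tables[[1]]))
}

#' Build a CommunityLabeling from planted ground truth
#'
#' Turns the generator's per-cell planted community assignment into a
#' \linkS4class{CommunityLabeling} (useful for evaluating detection, or for
#' running enrichment within a known community).
#'
#' @param truth data.frame from [generateTissue()] (or a row-bound cohort),
#'   in the same cell order as the cells.
#' @param cells the matching \linkS4class{CellTable}.
#' @return A \linkS4class{CommunityLabeling}; community ids are 1..K by
#'   decreasing size, with the planted names in
#'   \code{params$community_names}.
#' @export
labelingFromGroundTruth <- function(truth, cells) {
  f <- factor(truth$community)
  raw <- as.integer(f)
  lab <- .makeLabeling(raw, NULL, cellTypes(cells),
                       cellTypePalette(cells),
                       params = list(method = "ground_truth"))
  # recover which planted name each canonical id corresponds to
  nm <- character(nCommunities(lab))
  for (i in seq_len(nCommunities(lab)))
    nm[i] <- as.character(f[communityLabels(lab) == i][1])
  lab@params$community_names <- nm
  lab
}
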