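#' Upsample a similarity field to image resolution
#'
#' Bilinear upsampling of the H x W activation map to
#' `image_side x image_side`, so it can be overlaid on the input image.
#'
#' @param field A `similarity_field` from [compute_similarity_fields()].
#' @param image_side Target side in pixels.
#' @return `image_side x image_side` numeric matrix.
#' @export
upsample_activation <- function(field, image_side) {
  map <- field$map
  if (nrow(map) == 1 && ncol(map) == 1)
    return(matrix(map[1, 1], image_side, image_side))
  m <- EBImage::resize(map, w = image_side, h = image_side, filter = "bilinear")
  matrix(m, image_side, image_side)
}

# 4-connected component labeling of a logical matrix; returns an integer
# matrix of labels (0 = background).
label_components4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  stack <- integer(h * w)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L; stack[1] <- start; lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- (p - 1L) %% h + 1L; cc <- (p - 1L) %/% h + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                  if (cc > 1L) p - h, if (cc < w) p + h)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur; top <- top + 1L; stack[top] <- q
        }
      }
    }
  }
  lab
}

#' Evidence bounding box of an activation map
#'
#' Thresholds the map strictly above the given percentile (falling back to
#' ties-included when everything ties, so the set is never empty), keeps the
#' largest 4-connected component, and returns its tight bounding box in
#' 0-based half-open pixel coordinates.
#'
#' @param upsampled_map Numeric matrix (image resolution).
#' @param percentile Threshold percentile in (0, 100); default 95.
#' @return A `patch_box`.
#' @export
evidence_box <- function(upsampled_map, percentile = 95) {
  if (percentile <= 0 || percentile >= 100)
    abort_config("percentile must be in (0, 100)")
  thr <- quantile(upsampled_map, percentile / 100, names = FALSE)
  mask <- upsampled_map > thr
  if (!any(mask)) mask <- upsampled_map >= thr  # all-tie guard
  lab <- label_components4(mask)
  sizes <- tabulate(lab)
  best <- which.max(sizes)
  idx <- which(lab == best)
  h <- nrow(upsampled_map)
  r <- (idx - 1L) %% h + 1L; cc <- (idx - 1L) %/% h + 1L
  patch_box(top = min(r) - 1L, left = min(cc) - 1L,
            bottom = max(r), right = max(cc))
}

box_center <- function(box) c((box$top + box$bottom) / 2, (box$left + box$right) / 2)

#' Explain a prediction as ranked prototype evidence
#'
#' Runs the full forward pass and decomposes every class logit into
#' per-prototype contributions `similarity x head_weight`; for each class the
#' contributions plus the bias reconstruct the logit exactly (the operational
#' form of intrinsic interpretability). Each evidence item carries the image
#' region where the prototype's upsampled activation is strongest and, from
#' projection provenance, the training patch the prototype equals.
#'
#' @param image An [image_sample()] (resized internally if needed).
#' @param model A trained `leafproto_model` with projected prototypes.
#' @param percentile Percentile for [evidence_box()].
#' @return A `reasoning_report`: `image_id`, `predicted_class`, `logits`,
#'   and `per_class` — for each class its `logit`, `bias` and evidence items
#'   sorted by decreasing contribution.
#' @export
explain <- function(image, model, percentile = 95) {
  if (is.null(model$bank$provenance))
    stop("prototypes are not projected; run the push step (project_prototypes) first",
         call. = FALSE)
  image <- resize_sample(image, model$backbone$input_side)
  vol <- extract_features(image, model$backbone, model$params)
  fields <- compute_similarity_fields(vol, model$bank)
  pred <- predict_volume(vol, model$bank, model$head)
  side <- model$backbone$input_side
  ups <- lapply(fields, upsample_activation, image_side = side)
  boxes <- lapply(ups, evidence_box, percentile = percentile)
  m <- nrow(model$bank$vectors)
  per_class <- lapply(seq_len(model$n_classes), function(cl) {
    items <- lapply(seq_len(m), function(j) {
      prov <- model$bank$provenance[[j]]
      list(prototype_id = j,
           prototype_class = model$bank$class_of[j],
           similarity = fields[[j]]$max_score,
           head_weight = model$head$weight[j, cl],
           contribution = fields[[j]]$max_score * model$head$weight[j, cl],
           evidence_box = boxes[[j]],
           prototype_source = list(image_id = prov$image_id,
                                   box = prov$pixel_box))
    })
    items <- items[order(vapply(items, function(e) e$contribution, 0),
                         decreasing = TRUE)]
    list(class = cl - 1L, logit = pred$logits[cl], bias = model$head$bias[cl],
         evidence = items)
  })
  structure(list(image_id = image$image_id,
                 predicted_class = pred$predicted_class,
                 logits = pred$logits,
                 probabilities = pred$probabilities,
                 per_class = per_class),
            class = "reasoning_report")
}

#' Top evidence item for a class
#'
#' @param report A `reasoning_report`.
#' @param class Class index (0-based); defaults to the predicted class.
#' @param own_class_only Restrict to prototypes belonging to that class.
#' @return The highest-contribution evidence item.
#' @export
top_evidence <- function(report, class = report$predicted_class,
                         own_class_only = TRUE) {
  items <- report$per_class[[class + 1L]]$evidence
  if (own_class_only)
    items <- Filter(function(e) e$prototype_class == class, items)
  items[[1]]
}

#' Write a reasoning report (and optional overlays) to disk
#'
#' The report is serialized as JSON; if `image` is given, heat-map overlays
#' of the predicted class's top prototypes are written as PNGs (activation
#' in red blended over the image, evidence box edges marked).
#'
#' @param report A `reasoning_report`.
#' @param dir Output directory.
#' @param image Optional [image_sample()] to render overlays for.
#' @param model Model used to produce `report` (needed for overlays).
#' @param top_k Number of top own-class prototypes to render.
#' @return Invisibly, the JSON path.
#' @export
write_reasoning_report <- function(report, dir, image = NULL, model = NULL,
                                   top_k = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- lapply(report$per_class, function(pc) {
    list(class = pc$class, logit = pc$logit, bias = pc$bias,
         evidence = lapply(pc$evidence, function(e) {
           e$evidence_box <- unclass(e$evidence_box)
           if (!is.null(e$prototype_source$box))
             e$prototype_source$box <- unclass(e$prototype_source$box)
           e
         }))
  })
  path <- file.path(dir, paste0("report_", report$image_id, ".json"))
  write_json_file(list(image_id = report$image_id,
                       predicted_class = report$predicted_class,
                       logits = report$logits,
                       probabilities = report$probabilities,
                       per_class = json), path)
  if (!is.null(image) && !is.null(model)) {
    image <- resize_sample(image, model$backbone$input_side)
    vol <- extract_features(image, model$backbone, model$params)
    fields <- compute_similarity_fields(vol, model$bank)
    items <- report$per_class[[report$predicted_class + 1L]]$evidence
    items <- Filter(function(e) e$prototype_class == report$predicted_class, items)
    for (e in head(items, top_k)) {
      up <- upsample_activation(fields[[e$prototype_id]], model$backbone$input_side)
      up <- (up - min(up)) / max(max(up) - min(up), 1e-12)
      ov <- image$pixels * 0.55
      ov[, , 1] <- clamp01(ov[, , 1] + 0.45 * up)
      b <- e$evidence_box
      rs <- (b$top + 1):b$bottom; cs <- (b$left + 1):b$right
      edge_col <- c(1, 1, 0)
      for (ch in 1:3) {
        ov[rs, c(cs[1], cs[length(cs)]), ch] <- edge_col[ch]
        ov[c(rs[1], rs[length(rs)]), cs, ch] <- edge_col[ch]
      }
      png::writePNG(clamp01(ov),
                    file.path(dir, sprintf("overlay_%s_p%02d.png",
                                           report$image_id, e$prototype_id)))
    }
  }
  invisible(path)
}
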