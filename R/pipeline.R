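# End-to-end orchestration: seeded synthetic inputs, staged analysis with
# tabular outputs and a content-hash manifest.

#' Write / read a cohort of contact sets as TSV
#'
#' Long format, one row per contact: `receptor_accession`,
#' `gprotein_accession`, `gprotein_family`, `receptor_label`,
#' `galpha_label`, `structures` (comma-joined provenance).
#'
#' @param sets named list of `contact_set`s
#' @param path TSV path
#' @return `path` / the reconstructed named list
#' @export
write_contact_sets <- function(sets, path) {
  long <- do.call(rbind, lapply(sets, function(cs) {
    if (nrow(cs$contacts) == 0) return(NULL)
    data.frame(receptor_accession = cs$receptor_accession,
               gprotein_accession = cs$gprotein_accession,
               gprotein_family = cs$gprotein_family,
               receptor_label = cs$contacts$receptor_label,
               galpha_label = cs$contacts$galpha_label,
               structures = paste(cs$structures, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write_tsv(long, path)
}

#' @rdname write_contact_sets
#' @export
read_contact_sets <- function(path) {
  long <- read_tsv(path, colClasses = "character")
  key <- paste(long$receptor_accession, long$gprotein_accession, sep = "|")
  out <- lapply(split(long, key), function(g) {
    contact_set(g$receptor_accession[1], g$gprotein_accession[1],
                g[, c("receptor_label", "galpha_label")],
                gprotein_family = g$gprotein_family[1],
                structures = strsplit(g$structures[1], ",", fixed = TRUE)[[1]])
  })
  out[order(names(out))]
}

#' Default pipeline configuration
#'
#' All tunable parameters of a pipeline run with their defaults: the 8 A
#' contact cutoff, standard LOR variant with the 10% / |LOR|>2 feature
#' filter, k=2 fingerprint clusters, k=3 pose clusters (with two planted
#' pose groups the third cluster splits within-group variation), 999
#' permutations for both tests, and the synthetic generator settings
#' (cohort sizes, planted probabilities, pose transforms, noise).
#'
#' @param ... overrides for individual entries; unknown names are an error
#' @return named list of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1,
    contact_cutoff = 8.0,
    lor_variant = "standard",
    min_frequency = 0.10,
    min_abs_lor = 2,
    k_fingerprint = 2,
    k_pose = 2,
    n_permutations = 999,
    cohort_n_per_group = c("Gs" = 20, "Gi/o" = 20),
    cohort_n_enriched = 15,
    cohort_p_in = 0.8,
    cohort_p_out = 0.2,
    pose_n_per_group = 6,
    pose_sigma = 0.5,
    pose_translation = c(12, 0, 0),
    template_n_receptor = 42,
    template_n_galpha = 30,
    qc = qc_config(),
    sasa_points = 60
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(over)] <- over
  stopifnot(cfg$contact_cutoff > 0, cfg$min_frequency >= 0,
            cfg$n_permutations >= 1, cfg$k_fingerprint >= 2,
            cfg$k_pose >= 2)
  structure(cfg, class = "run_config")
}

.pipeline_stages <- c("simulate", "contacts", "fingerprint", "enrich",
                      "network", "permanova", "pose", "qc")

.need <- function(outdir, files, stage, dep) {
  paths <- file.path(outdir, files)
  if (!all(file.exists(paths))) {
    stop(sprintf("stage '%s' needs outputs of stage '%s' (missing: %s)",
                 stage, dep, paste(files[!file.exists(paths)],
                                   collapse = ", ")), call. = FALSE)
  }
  invisible(paths)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order
#' (`simulate`, `contacts`, `fingerprint`, `enrich`, `network`,
#' `permanova`, `pose`, `qc`), writing every artifact as a plain-text
#' table (or JSON) under `outdir` and finishing with a `manifest.json`
#' listing each artifact with its MD5 content hash. Each stage draws from
#' its own RNG stream derived from the master seed, so re-running a subset
#' of stages does not perturb the others. A full run with a fixed seed is
#' bit-reproducible.
#'
#' @param config a [run_config()]
#' @param stages subset of stages to run
#' @param outdir output directory (created if needed)
#' @return invisibly, the manifest as a data frame (`file`, `md5`)
#' @export
run_pipeline <- function(config = run_config(),
                         stages = .pipeline_stages, outdir) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "structures"), showWarnings = FALSE)
  sseed <- function(stage) derive_seed(config$seed,
                                       match(stage, .pipeline_stages))
  params <- contact_params(config$contact_cutoff)

  if ("simulate" %in% stages) {
    message("[simulate] generating synthetic cohort, poses and models")
    tmpl <- make_template(config$template_n_receptor,
                          config$template_n_galpha,
                          seed = sseed("simulate"))
    cohort <- sample_contact_cohort(cohort_spec(
      n_per_group = config$cohort_n_per_group,
      n_enriched = config$cohort_n_enriched,
      p_in = config$cohort_p_in, p_out = config$cohort_p_out,
      seed = sseed("simulate")))
    write_contact_sets(cohort$contact_sets,
                       file.path(outdir, "cohort_contacts.tsv"))
    write_tsv(cohort$coupling_map, file.path(outdir, "coupling_map.tsv"))
    jsonlite::write_json(list(enriched = cohort$enriched,
                              expected_lor = cohort$expected_lor),
                         file.path(outdir, "cohort_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    ens <- sample_pose_ensemble(
      tmpl,
      transforms = list(
        Gs = list(rotation = diag(3), translation = c(0, 0, 0)),
        `Gi/o` = list(rotation = diag(3),
                      translation = config$pose_translation)),
      n_per_group = config$pose_n_per_group, sigma = config$pose_sigma,
      seed = sseed("simulate"))
    for (id in names(ens$structures)) {
      write_complex(ens$structures[[id]],
                    file.path(outdir, "structures", paste0(id, ".pdb")))
    }
    write_tsv(ens$mapping, file.path(outdir, "pose_mapping.tsv"))
    write_tsv(data.frame(structure_id = names(ens$groups),
                         group = unname(ens$groups)),
              file.path(outdir, "pose_groups.tsv"))
    mset <- sample_model_set(tmpl, seed = sseed("simulate"))
    for (id in names(mset$models)) {
      write_complex(mset$models[[id]]$structure,
                    file.path(outdir, "structures", paste0(id, ".pdb")))
    }
    write_tsv(mset$mapping, file.path(outdir, "model_mapping.tsv"))
    jsonlite::write_json(
      lapply(mset$models, function(m)
        list(ptm = m$ptm, iptm = m$iptm, plddt = as.list(m$plddt))),
      file.path(outdir, "model_metrics.json"), auto_unbox = TRUE,
      digits = NA)
    write_tsv(mset$expected, file.path(outdir, "model_truth.tsv"))
  }

  if ("contacts" %in% stages) {
    message("[contacts] extracting interface contacts from structures")
    .need(outdir, c("pose_mapping.tsv", "pose_groups.tsv"),
          "contacts", "simulate")
    mapping <- read_mapping_table(file.path(outdir, "pose_mapping.tsv"))
    grp <- read_tsv(file.path(outdir, "pose_groups.tsv"))
    sets <- lapply(grp$structure_id, function(id) {
      st <- load_complex(file.path(outdir, "structures",
                                   paste0(id, ".pdb")),
                         structure_id = id)
      st$receptor_chain <- "R"; st$galpha_chain <- "G"
      st$receptor_accession <- sprintf("R_%s", id)
      st$gprotein_accession <- "GA"
      st$gprotein_family <- grp$group[grp$structure_id == id]
      suppressWarnings(interface_contacts(st, mapping, params))
    })
    names(sets) <- vapply(sets, complex_key, character(1))
    write_contact_sets(sets, file.path(outdir, "structure_contacts.tsv"))
    freq <- contact_frequency(sets)
    write_tsv(freq, file.path(outdir, "contact_frequency.tsv"))
  }

  if ("fingerprint" %in% stages) {
    message("[fingerprint] building CF fingerprints")
    .need(outdir, "cohort_contacts.tsv", "fingerprint", "simulate")
    sets <- read_contact_sets(file.path(outdir, "cohort_contacts.tsv"))
    fp <- build_fingerprints(sets, mode = "CF")
    df <- data.frame(complex = rownames(fp),
                     group = attr(fp, "groups")[rownames(fp)],
                     as.data.frame(fp, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(outdir, "fingerprints.tsv"))
  }

  if ("enrich" %in% stages) {
    message("[enrich] LOR enrichment, informative filter, clustering")
    .need(outdir, "fingerprints.tsv", "enrich", "fingerprint")
    df <- read_tsv(file.path(outdir, "fingerprints.tsv"))
    fp <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(fp) <- df$complex
    groups <- stats::setNames(df$group, df$complex)
    enr <- enrichment_table(fp, groups, variant = config$lor_variant)
    write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    kept <- filter_informative(fp, enr, config$min_frequency,
                               config$min_abs_lor)
    labels <- cluster_fingerprints(kept, k = config$k_fingerprint)
    write_tsv(data.frame(complex = names(labels),
                         cluster = as.integer(labels)),
              file.path(outdir, "fingerprint_clusters.tsv"))
    cmap <- read_tsv(file.path(outdir, "coupling_map.tsv"))
    prof <- cluster_coupling_profile(labels, cmap)
    write_tsv(prof, file.path(outdir, "cluster_coupling.tsv"))
  }

  if ("network" %in% stages) {
    message("[network] SSE networks and graph distance matrix")
    .need(outdir, "cohort_contacts.tsv", "network", "simulate")
    sets <- read_contact_sets(file.path(outdir, "cohort_contacts.tsv"))
    groups <- vapply(sets, `[[`, character(1), "gprotein_family")
    for (g in unique(groups)) {
      net <- build_sse_network(sets[groups == g], group = g)
      tag <- gsub("[^A-Za-z0-9]", "", g)
      write_tsv(net$nodes, file.path(outdir,
                                     sprintf("network_nodes_%s.tsv", tag)))
      write_tsv(net$edges, file.path(outdir,
                                     sprintf("network_edges_%s.tsv", tag)))
      write_tsv(node_betweenness(net),
                file.path(outdir, sprintf("network_stats_%s.tsv", tag)))
      igraph::write_graph(sse_network_igraph(net),
                          file.path(outdir,
                                    sprintf("network_%s.graphml", tag)),
                          format = "graphml")
    }
    d <- graph_distance_matrix(sets)
    write_tsv(data.frame(complex = rownames(d), as.data.frame(d),
                         check.names = FALSE),
              file.path(outdir, "graph_distances.tsv"))
  }

  if ("permanova" %in% stages) {
    message("[permanova] permutation tests on graph distances")
    .need(outdir, c("graph_distances.tsv", "cohort_contacts.tsv"),
          "permanova", "network")
    dd <- read_tsv(file.path(outdir, "graph_distances.tsv"))
    d <- as.matrix(dd[, -1, drop = FALSE])
    rownames(d) <- dd$complex
    sets <- read_contact_sets(file.path(outdir, "cohort_contacts.tsv"))
    groups <- vapply(sets, `[[`, character(1), "gprotein_family")[
      rownames(d)]
    pa <- permanova(d, groups, config$n_permutations,
                    seed = sseed("permanova"))
    pd <- permdisp(d, groups, config$n_permutations,
                   seed = sseed("permanova"))
    jsonlite::write_json(
      list(permanova = unclass(pa), permdisp = unclass(pd)),
      file.path(outdir, "permutation_tests.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  }

  if ("pose" %in% stages) {
    message("[pose] superposition, RMSD clustering, centroid, RMSF")
    .need(outdir, c("pose_mapping.tsv", "pose_groups.tsv"),
          "pose", "simulate")
    mapping <- read_mapping_table(file.path(outdir, "pose_mapping.tsv"))
    grp <- read_tsv(file.path(outdir, "pose_groups.tsv"))
    structures <- lapply(grp$structure_id, function(id) {
      st <- load_complex(file.path(outdir, "structures",
                                   paste0(id, ".pdb")), structure_id = id)
      st$receptor_chain <- "R"; st$galpha_chain <- "G"
      st
    })
    names(structures) <- grp$structure_id
    core <- build_consensus_core(structures, mapping)
    ens <- lapply(structures, structure_to_coordset, mapping = mapping,
                  core = core)
    groups <- stats::setNames(grp$group, grp$structure_id)
    d <- rmsd_matrix(ens, groups)
    write_tsv(data.frame(structure_id = rownames(d), as.data.frame(d),
                         check.names = FALSE),
              file.path(outdir, "pose_rmsd.tsv"))
    labels <- cluster_rmsd(d, k = config$k_pose)
    write_tsv(data.frame(structure_id = names(labels),
                         cluster = as.integer(labels),
                         group = groups[names(labels)]),
              file.path(outdir, "pose_clusters.tsv"))
    cents <- vapply(sort(unique(groups)), function(g)
      pose_centroid(d, names(groups)[groups == g]), character(1))
    write_tsv(data.frame(group = names(cents), centroid = unname(cents)),
              file.path(outdir, "pose_centroids.tsv"))
    rmsf_all <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
      members <- names(groups)[groups == g]
      prof <- rmsf_profile(ens[members], ens[[pose_centroid(d, members)]])
      cbind(group = g, prof, stringsAsFactors = FALSE)
    }))
    write_tsv(rmsf_all, file.path(outdir, "pose_rmsf.tsv"))
  }

  if ("qc" %in% stages) {
    message("[qc] composite model filter")
    .need(outdir, c("model_mapping.tsv", "model_metrics.json"),
          "qc", "simulate")
    mapping <- read_mapping_table(file.path(outdir, "model_mapping.tsv"))
    metrics <- jsonlite::read_json(file.path(outdir, "model_metrics.json"))
    models <- lapply(names(metrics), function(id) {
      st <- load_complex(file.path(outdir, "structures",
                                   paste0(id, ".pdb")), structure_id = id)
      st$receptor_chain <- "R"; st$galpha_chain <- "G"
      list(model_id = id, structure = st,
           plddt = unlist(metrics[[id]]$plddt),
           ptm = metrics[[id]]$ptm, iptm = metrics[[id]]$iptm)
    })
    res <- suppressWarnings(qc_filter(models, mapping, config$qc, params,
                                      sasa_points = config$sasa_points))
    write_tsv(res$audit, file.path(outdir, "qc_audit.tsv"))
    write_tsv(data.frame(model_id = res$survivors),
              file.path(outdir, "qc_survivors.tsv"))
  }

  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
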