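Package: bonecho
Title: Bone Cortical Segmentation and CT Registration in Tracked 3D Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of the bone cortical surface in 3D
    ultrasound volumes and surface-based rigid registration of a preoperative
    CT bone mesh. Sheet-like structures are enhanced with a Hessian-eigenvalue
    sheetness filter, voxels are classified into bone, soft tissue and acoustic
    shadow with a Gaussian Bayes (quadratic discriminant) classifier, and a
    single cortical surface is extracted by probability-ranked seeded region
    growing followed by isosurface meshing. The CT mesh is registered to the
    ultrasound surface by landmark initialization and iterative closest points.
    Includes volume and mesh I/O (NRRD, MetaImage, NIfTI, PLY, STL), a
    synthetic bone-phantom generator with known ground truth, and
    segmentation-error / target-registration-error evaluation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
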