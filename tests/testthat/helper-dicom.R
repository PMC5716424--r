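# Writes a small DICOM CT series using pydicom (the independent writer),
# so the package's reader is exercised against files produced by an
# unrelated implementation.

write_dicom_series <- function(dir, n_slices = 3, rows = 5, cols = 6,
                               slope = 1, intercept = -1024,
                               stored_value = 1024, rows_of_last = rows) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  script <- sprintf('
import numpy as np
from pydicom.dataset import Dataset, FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

out, n, rows, cols = %s, %d, %d, %d
slope, intercept, stored, rows_last = %s, %s, %d, %d
rng = np.random.default_rng(42)
series = generate_uid()
for inst in range(1, n + 1):
    r = rows_last if inst == n else rows
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = FileDataset(None, {}, file_meta=meta, preamble=b"\\0" * 128)
    ds.SOPClassUID = meta.MediaStorageSOPClassUID
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = series
    ds.Modality = "CT"
    ds.Rows, ds.Columns = r, cols
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleSlope = str(slope)
    ds.RescaleIntercept = str(intercept)
    ds.PixelSpacing = ["0.5", "1.0"]
    ds.SliceThickness = "2.5"
    ds.InstanceNumber = inst
    ds.ImagePositionPatient = ["0", "0", str(inst * 2.5)]
    arr = rng.integers(0, 2000, size=(r, cols)).astype("<u2")
    arr[0, 0] = stored
    ds.PixelData = arr.tobytes()
    np.savetxt(f"{out}/ref_{inst}.txt", arr, fmt="%%d")
    ds.save_as(f"{out}/slice_{inst}.dcm", enforce_file_format=True)
', deparse(dir), n_slices, rows, cols, format(slope), format(intercept),
     stored_value, rows_of_last)
  status <- system2(python, "-", input = script,
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  ## reference pixel matrices, then keep only the .dcm files in the series dir
  refs <- lapply(seq_len(n_slices), function(i) {
    f <- file.path(dir, sprintf("ref_%d.txt", i))
    m <- as.matrix(read.table(f))
    file.remove(f)
    dimnames(m) <- NULL
    m
  })
  refs
}
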