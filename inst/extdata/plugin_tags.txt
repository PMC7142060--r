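# DICOM tags exposed to plug-ins in metadata.txt (the PHI list is always
# subtracted last, so a keyword appearing on both lists is never exposed).
# Modality, geometry and acquisition parameters only — never identity tags.
Modality
SeriesDescription
SeriesInstanceUID
Rows
Columns
PixelSpacing
SliceThickness
KVP
RescaleSlope
RescaleIntercept
BitsAllocated
BitsStored
HighBit
PixelRepresentation
PhotometricInterpretation
SamplesPerPixel
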