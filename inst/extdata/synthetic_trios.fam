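fam00001	fam00001_f	0	0	0	1
fam00002	fam00002_f	0	0	0	1
fam00003	fam00003_f	0	0	0	1
fam00004	fam00004_f	0	0	0	1
fam00005	fam00005_f	0	0	0	1
fam00006	fam00006_f	0	0	0	1
fam00007	fam00007_f	0	0	0	1
fam00008	fam00008_f	0	0	0	1
fam00009	fam00009_f	0	0	0	1
fam00010	fam00010_f	0	0	0	1
fam00011	fam00011_f	0	0	0	1
fam00012	fam00012_f	0	0	0	1
fam00013	fam00013_f	0	0	0	1
fam00014	fam00014_f	0	0	0	1
fam00015	fam00015_f	0	0	0	1
fam00016	fam00016_f	0	0	0	1
fam00017	fam00017_f	0	0	0	1
fam00018	fam00018_f	0	0	0	1
fam00019	fam00019_f	0	0	0	1
fam00020	fam00020_f	0	0	0	1
fam00021	fam00021_f	0	0	0	1
fam00022	fam00022_f	0	0	0	1
fam00023	fam00023_f	0	0	0	1
fam00024	fam00024_f	0	0	0	1
fam00025	fam00025_f	0	0	0	1
fam00026	fam00026_f	0	0	0	1
fam00027	fam00027_f	0	0	0	1
fam00028	fam00028_f	0	0	0	1
fam00029	fam00029_f	0	0	0	1
fam00030	fam00030_f	0	0	0	1
fam00031	fam00031_f	0	0	0	1
fam00032	fam00032_f	0	0	0	1
fam00033	fam00033_f	0	0	0	1
fam00034	fam00034_f	0	0	0	1
fam00035	fam00035_f	0	0	0	1
fam00036	fam00036_f	0	0	0	1
fam00037	fam00037_f	0	0	0	1
fam00038	fam00038_f	0	0	0	1
fam00039	fam00039_f	0	0	0	1
fam00040	fam00040_f	0	0	0	1
fam00001	fam00001_m	0	0	0	1
fam00002	fam00002_m	0	0	0	1
fam00003	fam00003_m	0	0	0	1
fam00004	fam00004_m	0	0	0	1
fam00005	fam00005_m	0	0	0	1
fam00006	fam00006_m	0	0	0	1
fam00007	fam00007_m	0	0	0	1
fam00008	fam00008_m	0	0	0	1
fam00009	fam00009_m	0	0	0	1
fam00010	fam00010_m	0	0	0	1
fam00011	fam00011_m	0	0	0	1
fam00012	fam00012_m	0	0	0	1
fam00013	fam00013_m	0	0	0	1
fam00014	fam00014_m	0	0	0	1
fam00015	fam00015_m	0	0	0	1
fam00016	fam00016_m	0	0	0	1
fam00017	fam00017_m	0	0	0	1
fam00018	fam00018_m	0	0	0	1
fam00019	fam00019_m	0	0	0	1
fam00020	fam00020_m	0	0	0	1
fam00021	fam00021_m	0	0	0	1
fam00022	fam00022_m	0	0	0	1
fam00023	fam00023_m	0	0	0	1
fam00024	fam00024_m	0	0	0	1
fam00025	fam00025_m	0	0	0	1
fam00026	fam00026_m	0	0	0	1
fam00027	fam00027_m	0	0	0	1
fam00028	fam00028_m	0	0	0	1
fam00029	fam00029_m	0	0	0	1
fam00030	fam00030_m	0	0	0	1
fam00031	fam00031_m	0	0	0	1
fam00032	fam00032_m	0	0	0	1
fam00033	fam00033_m	0	0	0	1
fam00034	fam00034_m	0	0	0	1
fam00035	fam00035_m	0	0	0	1
fam00036	fam00036_m	0	0	0	1
fam00037	fam00037_m	0	0	0	1
fam00038	fam00038_m	0	0	0	1
fam00039	fam00039_m	0	0	0	1
fam00040	fam00040_m	0	0	0	1
fam00001	fam00001_c	fam00001_f	fam00001_m	0	2
fam00002	fam00002_c	fam00002_f	fam00002_m	0	2
fam00003	fam00003_c	fam00003_f	fam00003_m	0	2
fam00004	fam00004_c	fam00004_f	fam00004_m	0	2
fam00005	fam00005_c	fam00005_f	fam00005_m	0	2
fam00006	fam00006_c	fam00006_f	fam00006_m	0	2
fam00007	fam00007_c	fam00007_f	fam00007_m	0	2
fam00008	fam00008_c	fam00008_f	fam00008_m	0	2
fam00009	fam00009_c	fam00009_f	fam00009_m	0	2
fam00010	fam00010_c	fam00010_f	fam00010_m	0	2
fam00011	fam00011_c	fam00011_f	fam00011_m	0	2
fam00012	fam00012_c	fam00012_f	fam00012_m	0	2
fam00013	fam00013_c	fam00013_f	fam00013_m	0	2
fam00014	fam00014_c	fam00014_f	fam00014_m	0	2
fam00015	fam00015_c	fam00015_f	fam00015_m	0	2
fam00016	fam00016_c	fam00016_f	fam00016_m	0	2
fam00017	fam00017_c	fam00017_f	fam00017_m	0	2
fam00018	fam00018_c	fam00018_f	fam00018_m	0	2
fam00019	fam00019_c	fam00019_f	fam00019_m	0	2
fam00020	fam00020_c	fam00020_f	fam00020_m	0	2
fam00021	fam00021_c	fam00021_f	fam00021_m	0	2
fam00022	fam00022_c	fam00022_f	fam00022_m	0	2
fam00023	fam00023_c	fam00023_f	fam00023_m	0	2
fam00024	fam00024_c	fam00024_f	fam00024_m	0	2
fam00025	fam00025_c	fam00025_f	fam00025_m	0	2
fam00026	fam00026_c	fam00026_f	fam00026_m	0	2
fam00027	fam00027_c	fam00027_f	fam00027_m	0	2
fam00028	fam00028_c	fam00028_f	fam00028_m	0	2
fam00029	fam00029_c	fam00029_f	fam00029_m	0	2
fam00030	fam00030_c	fam00030_f	fam00030_m	0	2
fam00031	fam00031_c	fam00031_f	fam00031_m	0	2
fam00032	fam00032_c	fam00032_f	fam00032_m	0	2
fam00033	fam00033_c	fam00033_f	fam00033_m	0	2
fam00034	fam00034_c	fam00034_f	fam00034_m	0	2
fam00035	fam00035_c	fam00035_f	fam00035_m	0	2
fam00036	fam00036_c	fam00036_f	fam00036_m	0	2
fam00037	fam00037_c	fam00037_f	fam00037_m	0	2
fam00038	fam00038_c	fam00038_f	fam00038_m	0	2
fam00039	fam00039_c	fam00039_f	fam00039_m	0	2
fam00040	fam00040_c	fam00040_f	fam00040_m	0	2
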