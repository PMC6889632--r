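"specimen_id","species","genus","clades","fl_mm","hl_mm","age_min_ma","age_max_ma","onto_status"
"sp_001_s1","sp_001","sp","",440.700917746701,386.096130480942,191.172000929468,195.172000929468,"adult"
"sp_002_s1","sp_002","sp","",143.351062658326,112.013162105521,190.925217656134,194.925217656134,"adult"
"sp_003_s1","sp_003","sp","",166.949827462652,139.997991522644,135.156016587459,139.156016587459,"unknown"
"sp_004_s1","sp_004","sp","",169.784216606127,164.409488850723,120.538065023846,124.538065023846,"subadult"
"sp_005_s1","sp_005","sp","",169.78154681594,152.083922272069,120.538065023846,124.538065023846,"unknown"
"sp_006_s1","sp_006","sp","",126.27639369485,109.131053567384,132.482863676693,136.482863676693,"adult"
"sp_007_s1","sp_007","sp","",161.881219089585,90.6454763574222,124.597551935028,128.597551935028,"subadult"
"sp_007_s2","sp_007","sp","",132.286712682023,79.6149691292063,124.597551935028,128.597551935028,"adult"
"sp_008_s1","sp_008","sp","LongarmClade",173.545778796298,427.424235642241,120.538065023846,124.538065023846,"adult"
"sp_009_s1","sp_009","sp","LongarmClade",229.723452372737,749.324520142369,120.538065023846,124.538065023846,"unknown"
"sp_009_s2","sp_009","sp","LongarmClade",145.499303977174,470.659533635719,120.538065023846,124.538065023846,"juvenile"
"sp_009_s3","sp_009","sp","LongarmClade",174.865201782666,601.122158296985,120.538065023846,124.538065023846,"unknown"
"sp_010_s1","sp_010","sp","LongarmClade",124.896433235926,368.418637329241,120.538065023846,124.538065023846,"adult"
"sp_011_s1","sp_011","sp","LongarmClade",285.094046558018,967.14420647442,120.538065023846,124.538065023846,"adult"
"sp_012_s1","sp_012","sp","LongarmClade",239.993647196288,855.9775789003,120.538065023846,124.538065023846,"unknown"
"sp_012_s2","sp_012","sp","LongarmClade",186.068672526519,655.800611801428,120.538065023846,124.538065023846,"adult"
"sp_013_s1","sp_013","sp","LongarmClade",160.760093313629,536.969074335353,123.185162795702,127.185162795702,"subadult"
"sp_013_s2","sp_013","sp","LongarmClade",120.865432788412,421.500587789741,123.185162795702,127.185162795702,"unknown"
"sp_013_s3","sp_013","sp","LongarmClade",139.689940288795,504.28404313299,123.185162795702,127.185162795702,"unknown"
"sp_014_s1","sp_014","sp","",160.149924758403,84.4232601771393,120.538065023846,124.538065023846,"subadult"
"sp_014_s2","sp_014","sp","",99.0987634134518,47.9296988100756,120.538065023846,124.538065023846,"juvenile"
"sp_014_s3","sp_014","sp","",136.700082234466,71.4296899456593,120.538065023846,124.538065023846,"unknown"
"sp_015_s1","sp_015","sp","",146.891107107225,86.8926572989379,120.538065023846,124.538065023846,"adult"
"sp_016_s1","sp_016","sp","",145.494109274965,96.2764407895875,120.538065023846,124.538065023846,"subadult"
"sp_016_s2","sp_016","sp","",105.19981558093,73.540291436303,120.538065023846,124.538065023846,"unknown"
"sp_017_s1","sp_017","sp","",187.606321724116,124.493276068738,120.538065023846,124.538065023846,"adult"
"sp_017_s2","sp_017","sp","",125.642215508525,87.6547161136417,120.538065023846,124.538065023846,"juvenile"
"sp_017_s3","sp_017","sp","",158.18637908958,102.734790717589,120.538065023846,124.538065023846,"adult"
"sp_018_s1","sp_018","sp","NullClade1",600.698902258336,348.254610631674,142.164396775958,146.164396775958,"unknown"
"sp_018_s2","sp_018","sp","NullClade1",572.432064166997,362.695049429024,142.164396775958,146.164396775958,"adult"
"sp_019_s1","sp_019","sp","NullClade1",379.533980784067,191.285507375896,134.84302995267,138.84302995267,"unknown"
"sp_019_s2","sp_019","sp","NullClade1",256.268956760172,147.42689989273,134.84302995267,138.84302995267,"juvenile"
"sp_020_s1","sp_020","sp","NullClade1",272.547564153484,152.682123898109,135.36424921329,139.36424921329,"adult"
"sp_021_s1","sp_021","sp","NullClade1",411.345685437936,227.458724760865,120.538065023846,124.538065023846,"unknown"
"sp_021_s2","sp_021","sp","NullClade1",299.338983189127,154.496492910402,120.538065023846,124.538065023846,"adult"
"sp_022_s1","sp_022","sp","NullClade1",289.729101575433,168.678615097319,120.538065023846,124.538065023846,"adult"
"sp_022_s2","sp_022","sp","NullClade1",230.64590377312,155.122770632548,120.538065023846,124.538065023846,"subadult"
"sp_022_s3","sp_022","sp","NullClade1",171.185630777234,115.376627074881,120.538065023846,124.538065023846,"juvenile"
"sp_023_s1","sp_023","sp","NullClade1",322.829924643131,173.506564775422,120.538065023846,124.538065023846,"subadult"
"sp_023_s2","sp_023","sp","NullClade1",216.334987358611,123.486997901904,120.538065023846,124.538065023846,"juvenile"
"sp_024_s1","sp_024","sp","",232.009408778264,191.92576994929,126.844793757302,130.844793757302,"adult"
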